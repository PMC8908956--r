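# Brute-force RAF oracle, written directly from the definition and kept
# independent of the package's fixed-point implementation: reachability
# is simulated by firing reactions one at a time, the RA and F-generated
# conditions are checked literally, and the maxRAF is found by scoring
# every non-empty subset of reactions.

oracle_closure <- function(net, ids) {
  have <- net$food
  remaining <- ids
  repeat {
    progressed <- FALSE
    for (id in remaining) {
      r <- net$reactions[[id]]
      if (all(r$reactants %in% have) && !all(r$products %in% have)) {
        have <- union(have, r$products)
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  have
}

oracle_is_raf <- function(net, ids) {
  if (length(ids) == 0L) return(FALSE)
  reach <- oracle_closure(net, ids)
  for (id in ids) {
    if (!all(net$reactions[[id]]$reactants %in% reach)) return(FALSE)
  }
  made <- unlist(lapply(ids, function(id) net$reactions[[id]]$products))
  avail <- union(net$food, made)
  for (id in ids) {
    if (!any(net$reactions[[id]]$catalysts %in% avail)) return(FALSE)
  }
  TRUE
}

# all RAFs of a CRS by exhaustive subset enumeration (small |R| only)
oracle_all_rafs <- function(net) {
  ids <- names(net$reactions)
  n <- length(ids)
  out <- list()
  if (n == 0L) return(out)
  for (mask in seq_len(2^n - 1L)) {
    sub <- ids[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
    if (oracle_is_raf(net, sub)) out[[length(out) + 1L]] <- sub
  }
  out
}

# the maximum-cardinality RAF (empty character vector when none exists)
oracle_max_raf <- function(net) {
  rafs <- oracle_all_rafs(net)
  if (length(rafs) == 0L) return(character())
  rafs[[which.max(lengths(rafs))]]
}
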