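#' RAF decision: is a reaction subset a RAF?
#'
#' A non-empty subset `R'` of the reactions of a CRS is a RAF
#' (reflexively autocatalytic and F-generated) when
#' \enumerate{
#'   \item every reaction in `R'` is catalysed by at least one element
#'     that is in the foodset or produced by some reaction of `R'`
#'     (reflexive autocatalysis), and
#'   \item every reactant of every reaction in `R'` is reachable from the
#'     foodset using only reactions of `R'` (F-generated).
#' }
#' The empty set is not a RAF by definition.
#'
#' @param x a [crs] object.
#' @param subset character vector of reaction ids.
#' @return logical scalar.
#' @examples
#' toy2 <- parse_crs("food: a, b\nelements: a, b, ab\nr1: a + b -> ab [a]")
#' is_raf(toy2, "r1")          # TRUE: catalyst a is food
#' is_raf(toy2, character())   # FALSE: a RAF is non-empty
#' @export
is_raf <- function(x, subset) {
  subset <- check_subset(x, subset)
  if (length(subset) == 0L) return(FALSE)
  if (!is_f_generated(x, subset)) return(FALSE)
  avail <- union(x$food, products_of(x, subset))
  all(vapply(x$reactions[subset],
             function(r) any(r$catalysts %in% avail), logical(1)))
}

#' The maxRAF of a catalytic reaction system
#'
#' Every CRS that has a RAF has a unique maximal one, the maxRAF, which
#' contains every other RAF as a subset (the union of two RAFs is again a
#' RAF, so the collection of RAFs is a poset under inclusion with a single
#' top element).  The maxRAF is computed by the standard alternating
#' fixed-point reduction: starting from all reactions, repeatedly discard
#' reactions whose reactants are not producible from the foodset through
#' the surviving reactions, and reactions with no catalyst available in
#' the foodset or the survivors' products, until nothing changes.  A CRS
#' need not have a RAF; an empty result is reported as a distinct
#' "no RAF" status, not an error.
#'
#' @param x a [crs] object.
#' @param within optional character vector of reaction ids restricting
#'   the universe; the result is then the maxRAF of the sub-CRS spanned
#'   by those reactions.
#' @param prune_order `"closure_first"` (default) applies the
#'   reachability prune before the catalysis prune within each sweep;
#'   `"catalysis_first"` swaps them.  The fixed point is the same either
#'   way; the switch exists so that this can be asserted in tests.
#' @return an object of class `"raf_result"`: a list with
#'   `reaction_ids` (sorted character), `is_empty` (logical) and
#'   `iterations` (number of fixed-point sweeps performed).
#' @examples
#' toy1 <- parse_crs(paste(
#'   "food: a, b", "elements: a, b, ab, c",
#'   "r1: a + b -> ab [c]", "r2: a -> c [ab]", sep = "\n"))
#' max_raf(toy1)  # r1 and r2 sustain each other
#' @export
max_raf <- function(x, within = names(x$reactions),
                    prune_order = c("closure_first", "catalysis_first")) {
  prune_order <- match.arg(prune_order)
  survivors <- check_subset(x, within)
  iterations <- 0L
  prune_closure <- function(ids) {
    if (length(ids) == 0L) return(ids)
    cl <- producible_closure(x, ids)
    ids[vapply(x$reactions[ids],
               function(r) all(r$reactants %in% cl), logical(1))]
  }
  prune_catalysis <- function(ids) {
    if (length(ids) == 0L) return(ids)
    avail <- union(x$food, products_of(x, ids))
    ids[vapply(x$reactions[ids],
               function(r) any(r$catalysts %in% avail), logical(1))]
  }
  repeat {
    iterations <- iterations + 1L
    before <- survivors
    if (prune_order == "closure_first") {
      survivors <- prune_catalysis(prune_closure(survivors))
    } else {
      survivors <- prune_closure(prune_catalysis(survivors))
    }
    if (identical(survivors, before)) break
  }
  structure(
    list(reaction_ids = survivors,
         is_empty = length(survivors) == 0L,
         iterations = iterations),
    class = "raf_result"
  )
}

#' @export
print.raf_result <- function(x, ...) {
  if (x$is_empty) {
    cat("No RAF exists (", x$iterations, " fixed-point sweeps)\n", sep = "")
  } else {
    cat("maxRAF with ", length(x$reaction_ids), " reaction(s): ",
        paste(x$reaction_ids, collapse = ", "),
        "  [", x$iterations, " sweeps]\n", sep = "")
  }
  invisible(x)
}

#' Is a RAF closed?
#'
#' A closed RAF already contains every reaction of the whole network
#' whose reactants are all available — present in the foodset or produced
#' by some reaction of the RAF — and which has at least one available
#' catalyst.  Closed RAFs are stable unless the reaction set or the
#' foodset changes; a subRAF that is not closed is called transient.  The
#' maxRAF is always closed.
#'
#' @inheritParams is_raf
#' @return logical scalar.  Errors if `subset` is not a RAF.
#' @export
is_closed_raf <- function(x, subset) {
  subset <- check_subset(x, subset)
  if (!is_raf(x, subset)) stop("subset is not a RAF")
  length(supported_outside(x, subset)) == 0L
}

# reactions of the full network, outside `subset`, whose reactants and at
# least one catalyst lie in F u products(subset)
supported_outside <- function(x, subset) {
  avail <- union(x$food, products_of(x, subset))
  outside <- setdiff(names(x$reactions), subset)
  outside[vapply(x$reactions[outside], function(r) {
    all(r$reactants %in% avail) && any(r$catalysts %in% avail)
  }, logical(1))]
}

#' Closure of a subRAF
#'
#' Iteratively adds every network reaction whose reactants and at least
#' one catalyst become available from the growing set, until no further
#' reaction qualifies.  The result contains the original subRAF, is
#' itself a RAF, is closed, and the operation is idempotent.
#'
#' @inheritParams is_raf
#' @return sorted character vector of reaction ids (a closed RAF).
#' @export
closure_of_subraf <- function(x, subset) {
  subset <- check_subset(x, subset)
  if (!is_raf(x, subset)) stop("subset is not a RAF")
  current <- subset
  repeat {
    add <- supported_outside(x, current)
    if (length(add) == 0L) break
    current <- sort_tok(union(current, add))
  }
  current
}

#' Is a reaction set a co-RAF of a given RAF?
#'
#' A co-RAF of a RAF `R'` is a non-empty reaction set, disjoint from
#' `R'`, that is not a RAF on its own but forms a RAF when united with
#' `R'`.  Combination with a co-RAF is one of the three intrinsic ways a
#' RAF can expand (the others being union with another subRAF and closure
#' of a transient subRAF).
#'
#' @param x a [crs] object.
#' @param raf character vector of reaction ids forming a RAF.
#' @param candidate character vector of reaction ids, disjoint from
#'   `raf`.
#' @return logical scalar.
#' @export
is_co_raf <- function(x, raf, candidate) {
  raf <- check_subset(x, raf)
  candidate <- check_subset(x, candidate)
  if (!is_raf(x, raf)) stop("'raf' is not a RAF")
  if (length(intersect(raf, candidate))) {
    stop("'candidate' must be disjoint from 'raf'")
  }
  length(candidate) > 0L &&
    !is_raf(x, candidate) &&
    is_raf(x, union(raf, candidate))
}

# all RAF subsets of `ids` (exhaustive; caller enforces the size cap)
enumerate_rafs <- function(x, ids = names(x$reactions)) {
  ids <- check_subset(x, ids)
  n <- length(ids)
  out <- list()
  if (n == 0L) return(out)
  for (mask in seq_len(2^n - 1L)) {
    sub <- ids[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
    if (is_raf(x, sub)) out[[length(out) + 1L]] <- sub
  }
  out
}

#' Irreducible RAFs
#'
#' An irrRAF is a RAF with no proper non-empty subRAF.  In `"exhaustive"`
#' mode all irrRAFs are found by enumerating every non-empty reaction
#' subset (refused above `cap` reactions; the default cap of 12 keeps the
#' enumeration under 4096 subsets).  In `"sample"` mode, irrRAFs are
#' sampled by randomised single-reaction contraction: starting from the
#' maxRAF, repeatedly remove one reaction (in random order) and recompute
#' the maxRAF of the remainder, descending while a non-empty RAF
#' survives; when no single removal leaves a RAF, the current set is
#' irreducible.  Sampling may miss irrRAFs but every returned set is a
#' genuine irrRAF.
#'
#' @param x a [crs] object.
#' @param mode `"sample"` or `"exhaustive"`.
#' @param seed integer seed for the sampling mode.
#' @param restarts number of contraction restarts in sampling mode.
#' @param cap maximum number of reactions for exhaustive enumeration.
#' @return a list of sorted character vectors, one per distinct irrRAF,
#'   ordered lexicographically.  In exhaustive mode the attribute
#'   `"unique"` reports whether the network has a unique irrRAF.
#' @export
find_irr_rafs <- function(x, mode = c("sample", "exhaustive"),
                          seed = 1L, restarts = 100L, cap = 12L) {
  mode <- match.arg(mode)
  mr <- max_raf(x)
  if (mr$is_empty) stop("CRS has no RAF, so it has no irrRAF")
  if (mode == "exhaustive") {
    if (length(x$reactions) > cap) {
      stop("exhaustive irrRAF enumeration refused above ", cap,
           " reactions; use mode = \"sample\"")
    }
    rafs <- enumerate_rafs(x)
    irr <- Filter(function(s) {
      !any(vapply(rafs, function(t) {
        length(t) < length(s) && all(t %in% s)
      }, logical(1)))
    }, rafs)
    irr <- unique(irr)
    irr <- irr[order(vapply(irr, paste, character(1), collapse = " "))]
    attr(irr, "unique") <- length(irr) == 1L
    return(irr)
  }
  found <- list()
  set.seed(as.integer(seed))
  for (k in seq_len(restarts)) {
    current <- mr$reaction_ids
    repeat {
      shrunk <- FALSE
      for (r in sample(current)) {
        sub <- max_raf(x, within = setdiff(current, r))
        if (!sub$is_empty) {
          current <- sub$reaction_ids
          shrunk <- TRUE
          break
        }
      }
      if (!shrunk) break
    }
    found[[k]] <- current
  }
  irr <- unique(found)
  irr[order(vapply(irr, paste, character(1), collapse = " "))]
}

#' Can a RAF be written as the union of two smaller RAFs?
#'
#' A RAF is union-decomposable when it equals the union of two proper
#' non-empty subRAFs.  This holds exactly when every one of its reactions
#' belongs to some proper subRAF: taking a maximal proper subRAF `A` and,
#' for any reaction outside `A`, a proper subRAF containing it, their
#' union is a RAF strictly larger than `A` and hence the whole set.  For
#' RAFs of at most `cap` reactions the proper subRAFs are enumerated
#' exhaustively; above the cap, coverage is tested against sampled
#' irrRAFs, which can produce a false negative but never a false
#' positive.
#'
#' @inheritParams is_raf
#' @param cap size limit for the exhaustive route.
#' @param seed,restarts passed to [find_irr_rafs()] for the sampling
#'   route.
#' @return logical scalar.  An irrRAF is never decomposable.
#' @export
is_union_decomposable <- function(x, subset, cap = 12L,
                                  seed = 1L, restarts = 100L) {
  subset <- check_subset(x, subset)
  if (!is_raf(x, subset)) stop("subset is not a RAF")
  if (length(subset) == 1L) return(FALSE)
  if (length(subset) <= cap) {
    n <- length(subset)
    covered <- character()
    for (mask in seq_len(2^n - 2L)) {  # proper, non-empty subsets only
      sub <- subset[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
      if (length(sub) == n) next
      if (all(sub %in% covered)) next  # adds no new coverage
      if (is_raf(x, sub)) covered <- union(covered, sub)
      if (length(covered) == n) return(TRUE)
    }
    return(FALSE)
  }
  irr <- find_irr_rafs(x, mode = "sample", seed = seed, restarts = restarts)
  proper <- Filter(function(s) length(s) < length(subset) &&
                     all(s %in% subset), irr)
  length(proper) > 0L && all(subset %in% unique(unlist(proper)))
}
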