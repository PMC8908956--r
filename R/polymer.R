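#' Configuration for the binary polymer model
#'
#' The polymer model generates random catalytic reaction systems in
#' which elements are all strings of length at most `max_length` over a
#' small monomer alphabet, reactions are all ligations `x + y -> xy`
#' whose product does not exceed the maximum length, the foodset holds
#' all strings up to `food_max_length`, and each (element, reaction)
#' catalysis pair is included independently with probability
#' `catalysis_prob`.  The two parameters that drive the phase transition
#' from no RAF to an all-encompassing RAF are the catalysis probability
#' and the maximum polymer length.
#'
#' Catalysis is sampled with one uniform draw per (element, reaction)
#' pair from a stream determined solely by `seed` and the (fixed)
#' enumeration of elements and reactions; a pair is included when its
#' draw falls below `catalysis_prob`.  The catalysis set at a lower
#' probability is therefore a subset of the set at a higher probability
#' for the same seed, so maxRAF size is monotone in `catalysis_prob`
#' instance by instance, not merely on average.
#'
#' @param max_length maximum polymer length `n` (at least 2).
#' @param alphabet_size number of monomer types (default 2, letters
#'   `a`, `b`, ...; at most 26).
#' @param food_max_length maximum length `t` of foodset polymers
#'   (default 2; must be smaller than `max_length`).
#' @param catalysis_prob catalysis probability `p` in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return an object of class `"polymer_config"`.
#' @export
polymer_config <- function(max_length, alphabet_size = 2L,
                           food_max_length = 2L, catalysis_prob = 0,
                           seed = 1L) {
  stopifnot(alphabet_size >= 1L, alphabet_size <= 26L,
            max_length >= 2L, food_max_length >= 1L,
            food_max_length < max_length,
            catalysis_prob >= 0, catalysis_prob <= 1)
  structure(
    list(max_length = as.integer(max_length),
         alphabet_size = as.integer(alphabet_size),
         food_max_length = as.integer(food_max_length),
         catalysis_prob = catalysis_prob,
         seed = as.integer(seed)),
    class = "polymer_config"
  )
}

polymer_strings <- function(alphabet_size, max_length) {
  mono <- letters[seq_len(alphabet_size)]
  out <- vector("list", max_length)
  out[[1]] <- mono
  for (len in seq_len(max_length)[-1]) {
    out[[len]] <- as.vector(t(outer(out[[len - 1L]], mono, paste0)))
  }
  unlist(out)
}

#' Generate a polymer-model CRS
#'
#' @param config a [polymer_config()].
#' @return a [crs] object with all ligation reactions
#'   `x + y -> xy` (ordered pairs, `nchar(x) + nchar(y) <= max_length`),
#'   reaction ids `x_y`, and catalysis sampled as described in
#'   [polymer_config()].
#' @examples
#' cfg <- polymer_config(max_length = 4, catalysis_prob = 0.05, seed = 7)
#' g <- generate_polymer_crs(cfg)
#' length(g$elements)   # 30 strings over {a, b} of length <= 4
#' length(g$reactions)  # 68 ligations
#' @export
generate_polymer_crs <- function(config) {
  stopifnot(inherits(config, "polymer_config"))
  els <- polymer_strings(config$alphabet_size, config$max_length)
  food <- els[nchar(els) <= config$food_max_length]
  pairs <- list()
  for (x in els) {
    ys <- els[nchar(els) + nchar(x) <= config$max_length]
    for (y in ys) pairs[[length(pairs) + 1L]] <- c(x, y)
  }
  rx <- lapply(pairs, function(pr) {
    reaction(paste0(pr[1], "_", pr[2]), pr, paste0(pr[1], pr[2]))
  })
  # fixed canonical enumeration for the catalysis draws: elements and
  # reaction ids in radix order, draws consumed column-major, so the
  # draw for a given pair depends only on the seed, never on p
  el_sorted <- sort_tok(els)
  rid_sorted <- sort_tok(vapply(rx, function(r) r$id, character(1)))
  set.seed(config$seed)
  u <- matrix(stats::runif(length(el_sorted) * length(rid_sorted)),
              nrow = length(el_sorted),
              dimnames = list(el_sorted, rid_sorted))
  p <- config$catalysis_prob
  rx <- lapply(rx, function(r) {
    hit <- if (p >= 1) rep(TRUE, nrow(u)) else u[, r$id] < p
    r$catalysts <- el_sorted[hit]
    r
  })
  crs(elements = els, reactions = rx, food = food)
}

#' RAF-existence fraction across a catalysis-probability grid
#'
#' For each probability in `p_grid`, generates `replicates` polymer
#' CRSs (replicate `j` reuses seed `config$seed + j - 1` at every grid
#' point, preserving the per-instance monotone coupling) and records the
#' fraction with a non-empty maxRAF and the mean maxRAF size.
#'
#' @param config a [polymer_config()]; its `catalysis_prob` is ignored
#'   in favour of `p_grid`.
#' @param p_grid numeric vector of catalysis probabilities.
#' @param replicates number of instances per grid point (at least 1).
#' @return a `"transition_table"` data frame with columns `p`,
#'   `replicates`, `raf_fraction`, `mean_maxraf_size`.
#' @export
estimate_raf_probability <- function(config, p_grid, replicates = 50L) {
  stopifnot(inherits(config, "polymer_config"), replicates >= 1L,
            all(p_grid >= 0), all(p_grid <= 1))
  rows <- lapply(p_grid, function(p) {
    sizes <- vapply(seq_len(replicates), function(j) {
      cfg <- polymer_config(config$max_length, config$alphabet_size,
                            config$food_max_length, p,
                            seed = config$seed + j - 1L)
      mr <- max_raf(generate_polymer_crs(cfg))
      length(mr$reaction_ids)
    }, numeric(1))
    data.frame(p = p, replicates = replicates,
               raf_fraction = mean(sizes > 0),
               mean_maxraf_size = mean(sizes))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("transition_table", "data.frame")
  attr(out, "config") <- config
  out
}

#' Write a transition table as TSV
#'
#' The header comment records the generating configuration so a table
#' is self-describing.
#'
#' @param table an [estimate_raf_probability()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_transition_table <- function(table, path) {
  cfg <- attr(table, "config")
  hdr <- if (!is.null(cfg)) {
    sprintf("# polymer transition table: alphabet=%d max_length=%d food_max_length=%d base_seed=%d",
            cfg$alphabet_size, cfg$max_length, cfg$food_max_length, cfg$seed)
  } else {
    "# polymer transition table"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Small random CRS instances for fuzzing
#'
#' Generates an arbitrary (non-polymer) random CRS: `n_elements`
#' elements `e1, e2, ...`, of which a stated fraction (default 30%,
#' at least one) form the foodset; `n_reactions` reactions each with one
#' or two random reactants and one or two random products; and each
#' (element, reaction) catalysis pair included independently with
#' probability `p`.  Instances with few reactions feed the exhaustive
#' maxRAF oracle in tests.
#'
#' @param n_elements,n_reactions positive integers.
#' @param p catalysis probability in `[0, 1]`.
#' @param seed integer seed; the same seed reproduces the same CRS.
#' @param food_fraction fraction of elements placed in the foodset.
#' @return a [crs] object.
#' @export
random_crs <- function(n_elements, n_reactions, p, seed,
                       food_fraction = 0.3) {
  stopifnot(n_elements >= 1L, n_reactions >= 1L, p >= 0, p <= 1,
            food_fraction > 0, food_fraction <= 1)
  set.seed(as.integer(seed))
  els <- sprintf("e%02d", seq_len(n_elements))
  food <- sort_tok(sample(els, max(1L, round(food_fraction * n_elements))))
  rx <- lapply(seq_len(n_reactions), function(i) {
    reaction(sprintf("r%02d", i),
             reactants = sample(els, sample(1:2, 1), replace = TRUE),
             products = sample(els, sample(1:2, 1), replace = TRUE),
             catalysts = els[stats::runif(n_elements) < p])
  })
  crs(elements = els, reactions = rx, food = food)
}
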