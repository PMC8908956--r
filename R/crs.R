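#' Catalytic reaction systems
#'
#' A catalytic reaction system (CRS) is a tuple Q = (X, R, C, F): a set `X`
#' of element types, a set `R` of reactions, a catalysis assignment `C`
#' (here stored per reaction as the set of element types that catalyse it),
#' and a foodset `F` of elements present from the start.  In the cognitive
#' reading of the model, elements are mental representations, the foodset
#' holds innate or socially/individually learned representations, and
#' reactions are mental operations that combine or transform them.
#'
#' Reactants and products are multisets (an element may appear twice), but
#' availability is set-based: once an element is producible it is treated
#' as available in any multiplicity.  This matches the non-consumptive,
#' catalytic semantics of conceptual networks; stoichiometric bookkeeping
#' is deliberately out of scope.
#'
#' @param id reaction identifier, a token over `[A-Za-z0-9_]`.
#' @param reactants,products character vectors of element names
#'   (duplicates allowed, interpreted as multisets); both must be
#'   non-empty.
#' @param catalysts character vector of element names that catalyse the
#'   reaction; may be empty.  A reaction with no catalyst is legal in a
#'   CRS but can never belong to a RAF, since the reflexive-autocatalysis
#'   condition is then unsatisfiable.
#' @return `reaction()` returns an object of class `"crs_reaction"`;
#'   `crs()` returns an object of class `"crs"` with components
#'   `elements` (sorted character), `reactions` (named list of
#'   `crs_reaction`, sorted by id) and `food` (sorted character).
#' @examples
#' toy <- crs(
#'   elements = c("a", "b", "ab", "c"),
#'   reactions = list(
#'     reaction("r1", c("a", "b"), "ab", "c"),
#'     reaction("r2", "a", "c", "ab")
#'   ),
#'   food = c("a", "b")
#' )
#' toy
#' @export
crs <- function(elements, reactions, food) {
  if (is.null(reactions)) reactions <- list()
  rx <- lapply(reactions, function(r) {
    if (!inherits(r, "crs_reaction")) {
      r <- reaction(r$id, r$reactants, r$products, r$catalysts)
    }
    r
  })
  ids <- vapply(rx, function(r) r$id, character(1))
  names(rx) <- ids
  obj <- structure(
    list(
      elements = sort_tok(unique(as.character(elements))),
      reactions = rx[sort_tok(ids)],
      food = sort_tok(unique(as.character(food)))
    ),
    class = "crs"
  )
  validate_crs(obj)
}

#' @rdname crs
#' @export
reaction <- function(id, reactants, products, catalysts = character()) {
  structure(
    list(
      id = as.character(id),
      reactants = sort_tok(as.character(reactants)),
      products = sort_tok(as.character(products)),
      catalysts = sort_tok(unique(as.character(catalysts)))
    ),
    class = "crs_reaction"
  )
}

# canonical, locale-independent token ordering
sort_tok <- function(x) sort(x, method = "radix")

is_token <- function(x) grepl("^[A-Za-z0-9_]+$", x)

#' Validate CRS invariants
#'
#' Checks that element names are tokens and unique, reaction ids are
#' unique, every reactant, product and catalyst refers to a declared
#' element, reactant and product lists are non-empty, and the foodset is a
#' subset of the elements.  Errors on the first violation; returns the CRS
#' invisibly otherwise.
#'
#' @param x a `crs` object.
#' @return `x`, invisibly.
#' @export
validate_crs <- function(x) {
  stopifnot(inherits(x, "crs"))
  if (length(x$elements) == 0L) stop("CRS has no elements")
  bad <- x$elements[!is_token(x$elements)]
  if (length(bad)) {
    stop("invalid element name(s): ", paste(bad, collapse = ", "))
  }
  ids <- vapply(x$reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate reaction id: ", ids[duplicated(ids)][1L])
  }
  if (length(ids) && any(!is_token(ids))) {
    stop("invalid reaction id(s): ", paste(ids[!is_token(ids)], collapse = ", "))
  }
  missing_food <- setdiff(x$food, x$elements)
  if (length(missing_food)) {
    stop("foodset member(s) not declared as elements: ",
         paste(missing_food, collapse = ", "))
  }
  for (r in x$reactions) {
    if (length(r$reactants) == 0L) stop("reaction ", r$id, " has no reactants")
    if (length(r$products) == 0L) stop("reaction ", r$id, " has no products")
    refs <- c(r$reactants, r$products, r$catalysts)
    und <- setdiff(refs, x$elements)
    if (length(und)) {
      stop("reaction ", r$id, " references undeclared element(s): ",
           paste(und, collapse = ", "))
    }
  }
  invisible(x)
}

#' Advisory notes on a CRS
#'
#' Non-fatal observations a modeller may want surfaced: reactions with an
#' empty catalyst set (they can never join a RAF), and reactions in which
#' the same element appears as both a reactant and a catalyst (allowed by
#' the definitions, but worth flagging in a cognitive model where a
#' representation would be triggering its own transformation).
#'
#' @param x a `crs` object.
#' @return character vector of notes (possibly empty).
#' @export
crs_advisories <- function(x) {
  validate_crs(x)
  notes <- character()
  for (r in x$reactions) {
    if (length(r$catalysts) == 0L) {
      notes <- c(notes, paste0("reaction ", r$id,
                               " has no catalyst and can never belong to a RAF"))
    }
    both <- intersect(unique(r$reactants), r$catalysts)
    if (length(both)) {
      notes <- c(notes, paste0("reaction ", r$id,
                               ": element(s) ", paste(both, collapse = ", "),
                               " appear as both reactant and catalyst"))
    }
  }
  notes
}

#' @export
print.crs <- function(x, ...) {
  cat("Catalytic reaction system\n")
  cat("  elements:  ", length(x$elements), "\n", sep = "")
  cat("  foodset:   ", length(x$food),
      " (", paste(utils::head(x$food, 8), collapse = ", "),
      if (length(x$food) > 8) ", ..." else "", ")\n", sep = "")
  cat("  reactions: ", length(x$reactions), "\n", sep = "")
  invisible(x)
}

#' @export
print.crs_reaction <- function(x, ...) {
  cat(format_reaction(x), "\n")
  invisible(x)
}

format_reaction <- function(r) {
  line <- paste0(r$id, ": ", paste(r$reactants, collapse = " + "),
                 " -> ", paste(r$products, collapse = " + "))
  if (length(r$catalysts)) {
    line <- paste0(line, " [", paste(r$catalysts, collapse = ", "), "]")
  }
  line
}

#' Parse the CRS text format
#'
#' Reads the line-based plain-text CRS format.  `#` starts a comment that
#' runs to end of line; blank lines are ignored.  Recognised lines:
#' \describe{
#'   \item{`elements: e1, e2, ...`}{optional, repeatable; contributions
#'     are unioned.}
#'   \item{`food: e1, e2, ...`}{required (at least one), repeatable;
#'     unioned.  Food elements are implicitly declared.}
#'   \item{`id: r1 + r2 -> p1 + p2 [c1, c2]`}{a reaction; the catalyst
#'     bracket is optional; whitespace between tokens is insignificant.}
#' }
#' By default every element used in a reaction must have been declared on
#' an `elements:` or `food:` line, which catches typos in hand-written
#' files.  With `implicit_elements = TRUE`, elements are auto-declared
#' from use.
#'
#' @param text a single string or character vector of lines.
#' @param implicit_elements if `TRUE`, undeclared elements appearing in
#'   reactions are added to `X` instead of raising an error.
#' @return a validated [crs] object.
#' @seealso [write_crs()] for the canonical inverse.
#' @export
parse_crs <- function(text, implicit_elements = FALSE) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  declared <- character()
  food <- character()
  rx <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)[[:space:]]*:(.*)$", ln))[[1]]
    if (length(m) == 0L) stop("line ", i, ": malformed line: ", sQuote(ln))
    key <- m[2]
    body <- m[3]
    if (key == "elements") {
      declared <- union(declared, parse_token_list(body, i))
    } else if (key == "food") {
      food <- union(food, parse_token_list(body, i))
    } else {
      if (!is.null(rx[[key]])) stop("line ", i, ": duplicate reaction id: ", key)
      rx[[key]] <- parse_reaction_body(key, body, i)
    }
  }
  if (length(food) == 0L) stop("no food line")
  declared <- union(declared, food)
  used <- unique(unlist(lapply(rx, function(r) {
    c(r$reactants, r$products, r$catalysts)
  })))
  und <- setdiff(used, declared)
  if (length(und) && !implicit_elements) {
    stop("undeclared element(s) used in reactions: ",
         paste(sort_tok(und), collapse = ", "),
         " (declare them on an 'elements:' line, or parse with",
         " implicit_elements = TRUE)")
  }
  crs(elements = union(declared, und), reactions = rx, food = food)
}

parse_token_list <- function(body, lineno) {
  toks <- trimws(strsplit(body, ",", fixed = TRUE)[[1]])
  toks <- toks[toks != ""]
  if (length(toks) == 0L) stop("line ", lineno, ": empty name list")
  bad <- toks[!is_token(toks)]
  if (length(bad)) {
    stop("line ", lineno, ": invalid name(s): ", paste(bad, collapse = ", "))
  }
  toks
}

parse_reaction_body <- function(id, body, lineno) {
  body <- trimws(body)
  cat_m <- regmatches(body, regexec("^(.*)\\[(.*)\\][[:space:]]*$", body))[[1]]
  catalysts <- character()
  if (length(cat_m)) {
    catalysts <- parse_token_list(cat_m[3], lineno)
    body <- trimws(cat_m[2])
  }
  sides <- strsplit(body, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    stop("line ", lineno, ": reaction must contain exactly one '->': ",
         sQuote(body))
  }
  parse_side <- function(s) {
    toks <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    toks <- toks[toks != ""]
    if (length(toks) == 0L) {
      stop("line ", lineno, ": empty reactant or product list")
    }
    bad <- toks[!is_token(toks)]
    if (length(bad)) {
      stop("line ", lineno, ": invalid name(s): ", paste(bad, collapse = ", "))
    }
    toks
  }
  reaction(id, parse_side(sides[1]), parse_side(sides[2]), catalysts)
}

#' Write a CRS in canonical text form
#'
#' Canonical form: the `food:` line first, then a single `elements:` line,
#' then reactions sorted by id, with single spaces between tokens and
#' reactant/product/catalyst lists in sorted order.
#' `parse_crs(write_crs(x))` reproduces `x` exactly.
#'
#' @param x a `crs` object.
#' @param path optional file path; if supplied the document is written
#'   there and returned invisibly.
#' @return the document as a single string.
#' @export
write_crs <- function(x, path = NULL) {
  validate_crs(x)
  lines <- c(
    paste0("food: ", paste(x$food, collapse = ", ")),
    paste0("elements: ", paste(x$elements, collapse = ", ")),
    vapply(x$reactions, format_reaction, character(1))
  )
  doc <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(doc))
  }
  doc
}

#' Read a CRS document from a file
#'
#' @param path file path.
#' @inheritParams parse_crs
#' @return a validated [crs] object.
#' @export
read_crs <- function(path, implicit_elements = FALSE) {
  parse_crs(readLines(path, warn = FALSE), implicit_elements = implicit_elements)
}

# resolve a vector of reaction ids against a CRS, erroring on unknowns
check_subset <- function(x, subset) {
  subset <- unique(as.character(subset))
  unknown <- setdiff(subset, names(x$reactions))
  if (length(unknown)) {
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  }
  sort_tok(subset)
}

#' Foodset reachability (producible closure)
#'
#' The smallest superset `W` of the foodset such that any reaction in
#' `subset` whose reactants all lie in `W` contributes its products to
#' `W`.  Catalysis is ignored here: this is the pure reachability
#' primitive underlying the F-generated condition.  The result is a fixed
#' point, contains `F`, and is monotone in both the foodset and the
#' reaction subset.
#'
#' @param x a `crs` object.
#' @param subset character vector of reaction ids (defaults to all
#'   reactions).
#' @return sorted character vector of producible element names.
#' @examples
#' toy <- parse_crs("food: a\nelements: a, b, c\nr1: a -> b\nr2: b -> c")
#' producible_closure(toy, c("r1", "r2"))  # a, b, c
#' @export
producible_closure <- function(x, subset = names(x$reactions)) {
  subset <- check_subset(x, subset)
  avail <- x$food
  pending <- x$reactions[subset]
  repeat {
    fired <- vapply(pending, function(r) all(r$reactants %in% avail),
                    logical(1))
    if (!any(fired)) break
    avail <- union(avail,
                   unlist(lapply(pending[fired], function(r) r$products)))
    pending <- pending[!fired]
    if (length(pending) == 0L) break
  }
  sort_tok(avail)
}

#' Is a reaction subset F-generated?
#'
#' A subset is F-generated when every reactant of every reaction in it can
#' be produced from the foodset using only reactions of the subset itself.
#' The empty subset is vacuously F-generated.
#'
#' @inheritParams producible_closure
#' @return logical scalar.
#' @export
is_f_generated <- function(x, subset) {
  subset <- check_subset(x, subset)
  if (length(subset) == 0L) return(TRUE)
  cl <- producible_closure(x, subset)
  all(vapply(x$reactions[subset],
             function(r) all(r$reactants %in% cl), logical(1)))
}

# union of product sets of a reaction subset (assumed already checked)
products_of <- function(x, subset) {
  if (length(subset) == 0L) return(character())
  sort_tok(unique(unlist(lapply(x$reactions[subset],
                                function(r) r$products))))
}
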