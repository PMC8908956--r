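#' Lineage events
#'
#' A cultural lineage is an ordered sequence of events of three kinds,
#' applied to a population of individuals each carrying a conceptual
#' network split into a foodset `F_i` (mental representations that are
#' innate or acquired by social or individual learning) and a
#' foodset-derived set (representations produced by the individual's own
#' creative thought):
#' \describe{
#'   \item{`social`}{the actor acquires, from another individual, mental
#'     representations that individual already possesses.  The acquired
#'     copies enter the actor's *foodset*, even when the source obtained
#'     the original through creative thought: what is new information in
#'     the creator's mind is pre-existing information for the recipient.}
#'   \item{`individual`}{the actor acquires pre-existing information from
#'     the environment by non-social means; outputs enter the foodset.}
#'   \item{`creative`}{a catalysed mental operation `a (+ a') ->[b] c`
#'     transforms or combines representations the actor already possesses
#'     into a new one, which enters the actor's foodset-derived set.}
#' }
#'
#' @param step ordinal step number; several events may share a step (for
#'   example one cross-domain transfer reaction per through-line within a
#'   single conceptual step).
#' @param kind one of `"social"`, `"individual"`, `"creative"`.
#' @param actor individual id (token).
#' @param outputs character vector of new MR ids produced by the event.
#' @param inputs for `creative`, the reactant MR ids (must be possessed
#'   by the actor); for `social`, the source's MR ids being transmitted,
#'   element-wise parallel to `outputs`.
#' @param catalysts for `creative`, the catalyst MR ids (must be
#'   possessed by the actor); the catalyst is the need, desire or piece
#'   of knowledge that sparks the mental operation.
#' @param source for `social`, the id of the transmitting individual.
#' @return an object of class `"lineage_event"`.
#' @export
lineage_event <- function(step, kind, actor, outputs,
                          inputs = character(), catalysts = character(),
                          source = NA_character_) {
  kind <- match.arg(kind, c("social", "individual", "creative"))
  ev <- structure(
    list(step = as.integer(step), kind = kind, actor = as.character(actor),
         inputs = as.character(inputs), catalysts = as.character(catalysts),
         outputs = as.character(outputs),
         source = as.character(source)),
    class = "lineage_event"
  )
  if (length(ev$outputs) == 0L) stop("event has no outputs")
  if (kind == "creative") {
    if (length(ev$inputs) == 0L) stop("creative event needs inputs")
    if (length(ev$catalysts) == 0L) stop("creative event needs catalysts")
  }
  if (kind == "social") {
    if (is.na(ev$source)) stop("social event needs a source individual")
    if (length(ev$inputs) != length(ev$outputs)) {
      stop("social event needs one source MR per output MR")
    }
  }
  ev
}

#' @export
print.lineage_event <- function(x, ...) {
  cat(sprintf("step %d [%s] %s: %s -> %s%s%s\n",
              x$step, x$kind, x$actor,
              if (length(x$inputs)) paste(x$inputs, collapse = " + ") else "-",
              paste(x$outputs, collapse = " + "),
              if (length(x$catalysts))
                paste0(" [", paste(x$catalysts, collapse = ", "), "]") else "",
              if (!is.na(x$source)) paste0(" (from ", x$source, ")") else ""))
  invisible(x)
}

new_lineage_state <- function() {
  list(individuals = list(), mrs = list())
}

ensure_individual <- function(state, id) {
  if (is.null(state$individuals[[id]])) {
    state$individuals[[id]] <- list(foodset = character(),
                                    derived = character())
  }
  state
}

possessions <- function(state, id) {
  ind <- state$individuals[[id]]
  if (is.null(ind)) character() else c(ind$foodset, ind$derived)
}

register_mr <- function(state, id, owner, provenance, step,
                        source = NA_character_,
                        derived_from = character(),
                        catalyzed_by = character(),
                        background = FALSE) {
  if (!is.null(state$mrs[[id]])) {
    stop("mental representation id already in use: ", id)
  }
  state$mrs[[id]] <- list(id = id, owner = owner, provenance = provenance,
                          step = step, source = source,
                          derived_from = derived_from,
                          catalyzed_by = catalyzed_by,
                          background = background)
  state
}

#' Apply one lineage event to a population state
#'
#' Updates the per-individual foodset / foodset-derived partition.
#' Social and individual events grow the actor's foodset; creative events
#' grow the actor's foodset-derived set.  Creative events require all
#' inputs and catalysts to be already possessed by the actor (otherwise
#' the stream of thought is unreachable and an error is raised).  Social
#' events require the source to possess the transmitted representations;
#' a source individual never seen before (a teacher or long-dead carver
#' whose own history lies outside the modelled lineage) is auto-created
#' holding the transmitted items as background foodset knowledge.
#'
#' Events only ever add representations, and the foodset and derived set
#' of each individual stay disjoint.
#'
#' @param state a state as returned by `apply_event` or
#'   `new_lineage_state()` (internal list form).
#' @param event a [lineage_event].
#' @return the updated state.
#' @export
apply_event <- function(state, event) {
  stopifnot(inherits(event, "lineage_event"))
  state <- ensure_individual(state, event$actor)
  if (event$kind == "creative") {
    have <- possessions(state, event$actor)
    need <- unique(c(event$inputs, event$catalysts))
    missing <- setdiff(need, have)
    if (length(missing)) {
      stop("creative event for ", event$actor,
           " uses representation(s) not yet possessed (unreachable stream",
           " of thought): ", paste(missing, collapse = ", "))
    }
    for (out in event$outputs) {
      state <- register_mr(state, out, event$actor, "creative", event$step,
                           derived_from = event$inputs,
                           catalyzed_by = event$catalysts)
      ind <- state$individuals[[event$actor]]
      ind$derived <- union(ind$derived, out)
      state$individuals[[event$actor]] <- ind
    }
  } else if (event$kind == "individual") {
    for (out in event$outputs) {
      state <- register_mr(state, out, event$actor, "individual", event$step)
      ind <- state$individuals[[event$actor]]
      ind$foodset <- union(ind$foodset, out)
      state$individuals[[event$actor]] <- ind
    }
  } else {  # social
    src <- event$source
    if (is.null(state$individuals[[src]])) {
      # background individual: seed with the transmitted knowledge
      state <- ensure_individual(state, src)
      for (mr in event$inputs) {
        state <- register_mr(state, mr, src, "individual",
                             event$step, background = TRUE)
        ind <- state$individuals[[src]]
        ind$foodset <- union(ind$foodset, mr)
        state$individuals[[src]] <- ind
      }
    } else {
      missing <- setdiff(event$inputs, possessions(state, src))
      if (length(missing)) {
        stop("social event: source ", src, " does not possess ",
             paste(missing, collapse = ", "))
      }
    }
    for (k in seq_along(event$outputs)) {
      out <- event$outputs[[k]]
      state <- register_mr(state, out, event$actor, "social", event$step,
                           source = src,
                           derived_from = event$inputs[[k]])
      ind <- state$individuals[[event$actor]]
      ind$foodset <- union(ind$foodset, out)
      state$individuals[[event$actor]] <- ind
    }
  }
  state
}

#' Run a lineage and collect its provenance ledger
#'
#' Applies the events in step order (ties kept in input order) and
#' returns the final population state together with a ledger recording,
#' for every mental representation, its owner, provenance tag, origin
#' step, source individual and the representations it was derived from
#' and catalysed by.  Any event error is re-raised with the failing step
#' number.
#'
#' @param events a list of [lineage_event] objects, or a data frame in
#'   the lineage TSV layout (see [read_lineage_tsv()]).
#' @return an object of class `"lineage_run"`: a list with `state`
#'   (per-individual `foodset` and `derived` sets), `ledger` (a data
#'   frame) and `events` (the ordered event list).
#' @export
run_lineage <- function(events) {
  if (is.data.frame(events)) events <- events_from_frame(events)
  stopifnot(all(vapply(events, inherits, logical(1), "lineage_event")))
  if (length(events)) {
    events <- events[order(vapply(events, function(e) e$step, integer(1)))]
  }
  state <- new_lineage_state()
  for (ev in events) {
    state <- tryCatch(
      apply_event(state, ev),
      error = function(e) {
        stop("step ", ev$step, ": ", conditionMessage(e), call. = FALSE)
      }
    )
  }
  structure(list(state = state, ledger = build_ledger(state),
                 events = events),
            class = "lineage_run")
}

build_ledger <- function(state) {
  mrs <- state$mrs
  if (length(mrs) == 0L) {
    return(data.frame(mr = character(), owner = character(),
                      provenance = character(), step = integer(),
                      source = character(), derived_from = character(),
                      catalyzed_by = character(), background = logical(),
                      stringsAsFactors = FALSE))
  }
  join <- function(v) if (length(v)) paste(v, collapse = ";") else ""
  data.frame(
    mr = vapply(mrs, `[[`, character(1), "id"),
    owner = vapply(mrs, `[[`, character(1), "owner"),
    provenance = vapply(mrs, `[[`, character(1), "provenance"),
    step = vapply(mrs, `[[`, integer(1), "step"),
    source = vapply(mrs, `[[`, character(1), "source"),
    derived_from = vapply(mrs, function(m) join(m$derived_from), character(1)),
    catalyzed_by = vapply(mrs, function(m) join(m$catalyzed_by), character(1)),
    background = vapply(mrs, `[[`, logical(1), "background"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.lineage_run <- function(x, ...) {
  cat("Lineage run: ", length(x$events), " event(s), ",
      length(x$state$individuals), " individual(s)\n", sep = "")
  for (id in names(x$state$individuals)) {
    ind <- x$state$individuals[[id]]
    cat(sprintf("  %s: |F| = %d, |derived| = %d\n",
                id, length(ind$foodset), length(ind$derived)))
  }
  invisible(x)
}

#' Trace a mental representation back to the foodset
#'
#' Walks the provenance ledger from a representation back through the
#' `derived_from` links of creative products, stopping at foodset items
#' (provenance innate, social or individual).  The result is a finite
#' acyclic ancestry: row depth 0 is the queried representation, higher
#' depths are successively earlier ancestors.  A foodset representation
#' yields a single depth-0 row (a chain of length zero).
#'
#' @param run a [run_lineage()] result.
#' @param mr_id the representation to trace.
#' @return a data frame with columns `depth`, `mr`, `owner`,
#'   `provenance`, `step`.
#' @export
trace_origin <- function(run, mr_id) {
  stopifnot(inherits(run, "lineage_run"))
  mrs <- run$state$mrs
  if (is.null(mrs[[mr_id]])) stop("unknown mental representation: ", mr_id)
  rows <- list()
  seen <- character()
  frontier <- mr_id
  depth <- 0L
  while (length(frontier)) {
    if (any(frontier %in% seen)) {
      stop("cycle detected in provenance of ", mr_id)  # cannot happen for
    }                                                  # append-only lineages
    for (id in frontier) {
      m <- mrs[[id]]
      rows[[length(rows) + 1L]] <- data.frame(
        depth = depth, mr = m$id, owner = m$owner,
        provenance = m$provenance, step = m$step,
        stringsAsFactors = FALSE)
    }
    seen <- c(seen, frontier)
    nxt <- unlist(lapply(frontier, function(id) {
      m <- mrs[[id]]
      if (m$provenance == "creative") m$derived_from else character()
    }))
    frontier <- setdiff(unique(nxt), seen)
    depth <- depth + 1L
  }
  do.call(rbind, rows)
}

#' Project an individual's conceptual network onto a CRS
#'
#' Builds the catalytic reaction system of one individual: elements are
#' all mental representations the individual possesses, the foodset is
#' their `F_i`, and each of their creative events becomes one reaction
#' (inputs as reactants, outputs as products, catalysts as given).  RAF
#' analysis on the result asks whether, starting from the foodset, there
#' is a catalysed stream of thought culminating in each foodset-derived
#' representation.
#'
#' @param run a [run_lineage()] result.
#' @param actor individual id.
#' @return a [crs] object; its reaction ids are `s<step>_<first output>`.
#' @export
lineage_to_crs <- function(run, actor) {
  stopifnot(inherits(run, "lineage_run"))
  ind <- run$state$individuals[[actor]]
  if (is.null(ind)) stop("unknown actor: ", actor)
  creative <- Filter(function(e) e$kind == "creative" && e$actor == actor,
                     run$events)
  rx <- lapply(creative, function(e) {
    reaction(sprintf("s%d_%s", e$step, e$outputs[[1]]),
             e$inputs, e$outputs, e$catalysts)
  })
  crs(elements = c(ind$foodset, ind$derived),
      reactions = rx, food = ind$foodset)
}

# ---- lineage TSV dialect ----------------------------------------------

split_cell <- function(cell) {
  if (is.na(cell) || cell == "-" || cell == "") return(character())
  strsplit(cell, ";", fixed = TRUE)[[1]]
}

join_cell <- function(v) if (length(v) == 0L) "-" else paste(v, collapse = ";")

events_from_frame <- function(df) {
  need <- c("step", "kind", "actor", "inputs", "catalysts", "outputs",
            "source")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("lineage table lacks column(s): ", paste(miss, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    src <- df$source[[i]]
    if (!is.na(src) && (src == "-" || src == "")) src <- NA_character_
    lineage_event(step = df$step[[i]], kind = df$kind[[i]],
                  actor = df$actor[[i]],
                  inputs = split_cell(df$inputs[[i]]),
                  catalysts = split_cell(df$catalysts[[i]]),
                  outputs = split_cell(df$outputs[[i]]),
                  source = src)
  })
}

#' Read / write lineage event tables
#'
#' The lineage TSV dialect has columns `step`, `kind`, `actor`, `inputs`,
#' `catalysts`, `outputs`, `source`; multiple MR ids within a cell are
#' separated by `;`, and `-` marks an empty cell.  Lines starting with
#' `#` are comments.  Row order is the single source of temporal order
#' for events sharing a step.
#'
#' @param path file path.
#' @return `read_lineage_tsv()` returns a list of [lineage_event]
#'   objects; `write_lineage_tsv()` returns `path` invisibly.
#' @export
read_lineage_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  df$step <- as.integer(df$step)
  events_from_frame(df)
}

#' @rdname read_lineage_tsv
#' @param events a list of [lineage_event] objects.
#' @export
write_lineage_tsv <- function(events, path) {
  df <- data.frame(
    step = vapply(events, function(e) e$step, integer(1)),
    kind = vapply(events, function(e) e$kind, character(1)),
    actor = vapply(events, function(e) e$actor, character(1)),
    inputs = vapply(events, function(e) join_cell(e$inputs), character(1)),
    catalysts = vapply(events, function(e) join_cell(e$catalysts),
                       character(1)),
    outputs = vapply(events, function(e) join_cell(e$outputs), character(1)),
    source = vapply(events, function(e) {
      if (is.na(e$source)) "-" else e$source
    }, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
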