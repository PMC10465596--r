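#' Candidate-filter criteria
#'
#' The staged identification of the putative peptidergic LN ensemble as an
#' ordered predicate chain: (1) the neuron is an annotated LN; (2) its subtype
#' is the target morphological class ("patchy"); (3) it receives input from a
#' designated marker neuron set (e.g. the serotonergic CSD neurons); (4) its
#' best mean-normalized morphological similarity against a reference library
#' exceeds `nblast_threshold`; (5) its tracing status equals `traced_status`.
#' Cheap annotation predicates run before the geometric stage.
#'
#' @param stages character vector naming the stages to apply, in order.
#' @param subtype target subtype label (default "patchy").
#' @param marker_neurons ids of the marker neuron set (default "CSD").
#' @param nblast_threshold similarity threshold theta in (0, 1\] (default 0.80).
#' @param traced_status required tracing label (default "Traced").
#' @param scoring,sigma,spacing,k passed to [nblast()] / [to_dotprops()].
#' @return an object of class `al_filter_criteria`.
#' @export
filter_criteria <- function(stages = c("category", "subtype", "marker_input",
                                       "nblast", "traced"),
                            subtype = "patchy", marker_neurons = "CSD",
                            nblast_threshold = 0.80, traced_status = "Traced",
                            scoring = "parametric", sigma = 3000,
                            spacing = 1500, k = 5L) {
  al_assert(length(stages) > 0, "al_config_error", "stages must be non-empty")
  known <- c("category", "subtype", "marker_input", "nblast", "traced")
  bad <- setdiff(stages, known)
  al_assert(length(bad) == 0, "al_config_error",
            "unknown filter stage(s): %s", paste(bad, collapse = ", "))
  al_assert(nblast_threshold > 0 && nblast_threshold <= 1, "al_config_error",
            "nblast_threshold must lie in (0, 1], got %g", nblast_threshold)
  structure(list(stages = stages, subtype = subtype,
                 marker_neurons = marker_neurons,
                 nblast_threshold = nblast_threshold,
                 traced_status = traced_status, scoring = scoring,
                 sigma = sigma, spacing = spacing, k = as.integer(k)),
            class = "al_filter_criteria")
}

#' Run the staged candidate filter
#'
#' Applies the stages of a [filter_criteria()] in declared order to all
#' annotated neurons, recording per-stage survivor counts and eliminated ids.
#' Deterministic; survivors are returned sorted so the result is invariant to
#' neuron order.
#'
#' @param conn an `al_connectome`.
#' @param references list of reference morphologies (`al_skeleton` or
#'   `al_dotprops`); required when the `nblast` stage is enabled.
#' @param criteria an `al_filter_criteria`.
#' @return an object of class `al_filter_ledger` with `stages` (data.frame of
#'   stage, n_survivors, eliminated) and `candidates` (final id set).
#' @export
filter_candidates <- function(conn, references = NULL,
                              criteria = filter_criteria()) {
  al_assert(inherits(criteria, "al_filter_criteria"), "al_config_error",
            "criteria must come from filter_criteria()")
  if ("nblast" %in% criteria$stages) {
    al_assert(length(references) > 0, "al_config_error",
              "nblast stage enabled but no reference morphology provided")
    references <- lapply(references, function(r) {
      if (inherits(r, "al_dotprops")) r
      else to_dotprops(r, spacing = criteria$spacing, k = criteria$k)
    })
  }
  ann <- conn$annotations
  survivors <- sort(ann$neuron_id)
  ledger <- list()
  for (st in criteria$stages) {
    keep <- switch(
      st,
      category = {
        cat_of <- ann$category[match(survivors, ann$neuron_id)]
        survivors[cat_of == "LN"]
      },
      subtype = {
        sub_of <- ann$subtype[match(survivors, ann$neuron_id)]
        survivors[sub_of == criteria$subtype]
      },
      marker_input = {
        cx <- conn$connections
        marked <- unique(cx$post_neuron[cx$pre_neuron %in%
                                          criteria$marker_neurons])
        intersect(survivors, marked)
      },
      nblast = {
        survivors[vapply(survivors, function(id) {
          sk <- conn$skeletons[[id]]
          if (is.null(sk)) return(FALSE)
          dp <- to_dotprops(sk, spacing = criteria$spacing, k = criteria$k)
          best <- max(vapply(references, function(ref) {
            nblast(dp, ref, scoring = criteria$scoring,
                   sigma = criteria$sigma)$mean_normalized
          }, numeric(1)))
          best > criteria$nblast_threshold
        }, logical(1))]
      },
      traced = {
        status <- ann$tracing_status[match(survivors, ann$neuron_id)]
        survivors[status == criteria$traced_status]
      }
    )
    ledger[[length(ledger) + 1L]] <- data.frame(
      stage = st, n_survivors = length(keep),
      eliminated = paste(setdiff(survivors, keep), collapse = ", "))
    survivors <- sort(keep)
  }
  structure(list(stages = do.call(rbind, ledger), candidates = survivors),
            class = "al_filter_ledger")
}

#' @export
print.al_filter_ledger <- function(x, ...) {
  cat("<al_filter_ledger>\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-13s -> %d survivors\n", x$stages$stage[i],
                x$stages$n_survivors[i]))
  }
  cat(sprintf("  candidates: %s\n", paste(x$candidates, collapse = ", ")))
  invisible(x)
}
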