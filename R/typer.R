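#' Search the four marker databases against an input sequence set
#'
#' Runs replicon, relaxase, mate-pair-formation (MPF) and oriT searches,
#' resolves overlapping hits per category, and collapses subject ids to
#' marker family names (the id prefix before the first underscore, e.g.
#' `IncF_1` -> `IncF`).
#'
#' @param input FASTA path or sequence tibble (an assembly or a single
#'   reconstructed plasmid unit).
#' @param markers Named list with elements `replicon`, `relaxase`, `mpf`
#'   and `orit` (FASTA paths or tibbles).
#' @param min_marker_identity,min_marker_coverage Identity/coverage filters
#'   for replicon, relaxase and MPF hits (percent), default 80/80.
#' @param min_orit_identity,min_orit_coverage Filters for oriT hits,
#'   default 90/90.
#' @param marker_overlap_fraction Overlap tolerance passed to
#'   [resolve_overlaps()], default 0.1.
#' @return A list with `hits` (tibble of all retained hits) and `families`
#'   (named list of sorted unique family names per category).
#' @export
type_markers <- function(input, markers,
                         min_marker_identity = 80, min_marker_coverage = 80,
                         min_orit_identity = 90, min_orit_coverage = 90,
                         marker_overlap_fraction = 0.1) {
  needed <- c("replicon", "relaxase", "mpf", "orit")
  missing <- setdiff(needed, names(markers))
  if (length(missing)) {
    abort(paste0("missing marker database(s): ", paste(missing, collapse = ", ")))
  }
  contigs <- as_seq_tbl(input, arg = "input")
  one <- function(type, mi, mc) {
    mob_search(markers[[type]], contigs, min_identity = mi, min_coverage = mc,
               subject_type = type) |>
      resolve_overlaps(max_overlap_fraction = marker_overlap_fraction)
  }
  hits <- bind_rows(
    one("replicon", min_marker_identity, min_marker_coverage),
    one("relaxase", min_marker_identity, min_marker_coverage),
    one("mpf", min_marker_identity, min_marker_coverage),
    one("orit", min_orit_identity, min_orit_coverage)
  )
  families <- map(setNames(needed, needed), function(type) {
    sort(unique(marker_family(hits$subject_id[hits$subject_type == type])))
  })
  list(hits = hits, families = families)
}

#' Predict plasmid mobility from marker presence
#'
#' A plasmid is `conjugative` if it carries at least a relaxase and a
#' mate-pair-formation marker; `mobilizable` if it carries a relaxase or an
#' oriT but lacks the MPF marker (such plasmids can be transferred by
#' machinery supplied in trans); and `non_mobilizable` if it lacks both a
#' relaxase and an oriT.
#'
#' @param has_relaxase,has_mpf,has_orit Logical vectors (recycled).
#' @return Character vector with values `"conjugative"`, `"mobilizable"` or
#'   `"non_mobilizable"`.
#' @examples
#' predict_mobility(TRUE, TRUE, FALSE)
#' predict_mobility(c(TRUE, FALSE), FALSE, c(FALSE, TRUE))
#' @export
predict_mobility <- function(has_relaxase, has_mpf, has_orit) {
  n <- max(length(has_relaxase), length(has_mpf), length(has_orit))
  r <- rep_len(as.logical(has_relaxase), n)
  m <- rep_len(as.logical(has_mpf), n)
  o <- rep_len(as.logical(has_orit), n)
  ifelse(r & m, "conjugative",
         ifelse(r | o, "mobilizable", "non_mobilizable"))
}

#' Type plasmids and predict their transmissibility
#'
#' Runs the four marker searches on each input and compiles one report row
#' per input: replicon, relaxase and MPF family lists, oriT presence, and
#' the mobility classification from [predict_mobility()].
#'
#' @param inputs A single FASTA path/sequence tibble, or a named list of
#'   them (e.g. one per reconstructed plasmid unit).
#' @inheritParams type_markers
#' @return A `mob_typer` tibble: `input_id`, `replicon_types`,
#'   `relaxase_types`, `mpf_types`, `orit_found`, `mobility`, and per
#'   category the retained hit count.
#' @export
mob_typer <- function(inputs, markers,
                      min_marker_identity = 80, min_marker_coverage = 80,
                      min_orit_identity = 90, min_orit_coverage = 90) {
  if (!is.list(inputs) || is.data.frame(inputs)) {
    inputs <- list(input = inputs)
  }
  if (is.null(names(inputs))) {
    names(inputs) <- paste0("input_", seq_along(inputs))
  }
  rows <- imap(inputs, function(x, id) {
    tm <- type_markers(x, markers,
                       min_marker_identity = min_marker_identity,
                       min_marker_coverage = min_marker_coverage,
                       min_orit_identity = min_orit_identity,
                       min_orit_coverage = min_orit_coverage)
    fam <- tm$families
    tibble(
      input_id = id,
      replicon_types = paste_types(fam$replicon),
      relaxase_types = paste_types(fam$relaxase),
      mpf_types = paste_types(fam$mpf),
      orit_found = length(fam$orit) > 0,
      mobility = predict_mobility(length(fam$relaxase) > 0,
                                  length(fam$mpf) > 0,
                                  length(fam$orit) > 0),
      n_replicon_hits = sum(tm$hits$subject_type == "replicon"),
      n_relaxase_hits = sum(tm$hits$subject_type == "relaxase"),
      n_mpf_hits = sum(tm$hits$subject_type == "mpf"),
      n_orit_hits = sum(tm$hits$subject_type == "orit")
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("mob_typer", class(out))
  out
}

paste_types <- function(x) if (length(x) == 0) "-" else paste(x, collapse = ",")

#' Write a typing report to TSV
#'
#' @param results A `mob_typer` tibble from [mob_typer()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_typer_report <- function(results, path) {
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  readr::write_tsv(results, path)
  invisible(path)
}

#' Mobility class counts across typed inputs
#'
#' @param object A `mob_typer` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mob_typer <- function(object, ...) {
  as_tibble(object) |>
    count(.data$mobility) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$mobility, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "plasmids", title = "Predicted mobility") +
    ggplot2::theme_minimal()
}
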