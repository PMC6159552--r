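#' Map assembly contigs to their closed-genome replicon of origin
#'
#' Aligns each contig against the closed genome's replicons and keeps the
#' single best-matching replicon (highest total bit score; ties broken by
#' combined alignment length, then lexicographically smaller replicon id).
#' Contigs mapping with less than `min_identity` percent identity or less
#' than `min_coverage` percent of their length are discarded and excluded
#' from all downstream counts. When a simulated `truth` table is supplied it
#' bypasses alignment entirely.
#'
#' @param assembly FASTA path or sequence tibble of the draft assembly.
#' @param genome FASTA path or sequence tibble of the closed replicons
#'   (chromosome and plasmids). Ignored when `truth` is given.
#' @param min_identity,min_coverage Mapping thresholds (percent), default 50.
#' @param truth Optional truth tibble from [fragment_assembly()] with
#'   `contig_id` and `origin_replicon_id`.
#' @return Tibble `contig_id`, `replicon_id` (and, in alignment mode,
#'   `pct_identity`, `coverage`, `bit_score`).
#' @export
map_contigs_to_truth <- function(assembly, genome = NULL, min_identity = 50,
                                 min_coverage = 50, truth = NULL) {
  if (!is.null(truth)) {
    return(tibble(contig_id = as.character(truth$contig_id),
                  replicon_id = as.character(truth$origin_replicon_id)))
  }
  contigs <- as_seq_tbl(assembly, arg = "assembly")
  if (nrow(contigs) == 0) abort("empty assembly")
  reps <- as_seq_tbl(genome, arg = "genome")
  hits <- mob_search(reps, contigs, min_identity = 0, min_coverage = 0,
                     subject_type = "plasmid_ref", coverage_on = "subject")
  if (nrow(hits) == 0) {
    return(tibble(contig_id = character(), replicon_id = character(),
                  pct_identity = numeric(), coverage = numeric(),
                  bit_score = numeric()))
  }
  hits |>
    group_by(.data$contig_id, .data$subject_id) |>
    summarise(
      comb = list(resolve_overlaps(pick("start", "end", "bit_score",
                                        "pct_identity", "length"),
                                   max_overlap_fraction = 0)),
      .groups = "drop"
    ) |>
    mutate(
      bit_score = map_dbl(.data$comb, ~ sum(.x$bit_score)),
      aln_len = map_dbl(.data$comb, ~ sum(.x$length)),
      pct_identity = map_dbl(.data$comb, ~ sum(.x$pct_identity * .x$length) /
                               sum(.x$length)),
      contig_len = nchar(contigs$seq)[match(.data$contig_id, contigs$id)],
      coverage = 100 * .data$aln_len / .data$contig_len
    ) |>
    group_by(.data$contig_id) |>
    arrange(dplyr::desc(.data$bit_score), dplyr::desc(.data$aln_len),
            .data$subject_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    filter(.data$pct_identity >= min_identity,
           .data$coverage >= min_coverage) |>
    select("contig_id", replicon_id = "subject_id", "pct_identity",
           "coverage", "bit_score")
}

#' Base-level plasmid detection confusion counts
#'
#' Adds each assessed contig's length to tp/fp/tn/fn according to whether it
#' was predicted as plasmid (assigned to any plasmid unit) and whether it
#' truly derives from a plasmid replicon. Contigs without a truth mapping
#' (discarded during mapping) are excluded; predicted contigs must otherwise
#' all be present in the truth map.
#'
#' @param assignments Tibble with `contig_id`, `length` and `assigned_unit`
#'   (`"chromosome"` or a unit id), e.g. `tidy(mob_recon(...))`.
#' @param truth_map Tibble from [map_contigs_to_truth()].
#' @param chromosome_ids Replicon ids counted as chromosome; everything else
#'   in the truth map is a plasmid. Default `"chromosome"`.
#' @return A `mob_confusion` tibble: `tp`, `fp`, `tn`, `fn` (bases),
#'   `sensitivity`, `specificity`.
#' @export
base_confusion <- function(assignments, truth_map,
                           chromosome_ids = "chromosome") {
  stopifnot(all(c("contig_id", "length", "assigned_unit") %in%
                  names(assignments)))
  truth_of <- setNames(truth_map$replicon_id, truth_map$contig_id)
  assessed <- assignments |>
    filter(.data$contig_id %in% names(truth_of))
  if (nrow(assessed) == 0) {
    abort("no assessed contigs: truth map and assignments do not overlap")
  }
  x <- assessed |>
    mutate(
      pred_plasmid = .data$assigned_unit != "chromosome",
      true_plasmid = !(truth_of[.data$contig_id] %in% chromosome_ids)
    )
  out <- tibble(
    tp = sum(x$length[x$pred_plasmid & x$true_plasmid]),
    fp = sum(x$length[x$pred_plasmid & !x$true_plasmid]),
    tn = sum(x$length[!x$pred_plasmid & !x$true_plasmid]),
    fn = sum(x$length[!x$pred_plasmid & x$true_plasmid])
  ) |>
    mutate(
      sensitivity = ifelse(.data$tp + .data$fn > 0,
                           .data$tp / (.data$tp + .data$fn), NA_real_),
      specificity = ifelse(.data$tn + .data$fp > 0,
                           .data$tn / (.data$tn + .data$fp), NA_real_)
    )
  class(out) <- c("mob_confusion", class(out))
  out
}

#' Classify per-plasmid reconstruction events
#'
#' For each truth plasmid: `correct` — all of its contigs lie in a single
#' unit and that unit contains no chromosome or other-plasmid contigs;
#' `split` — its contigs are distributed over more than one unit (without a
#' merge); `merge` — some unit holding its contigs also holds foreign
#' (other-plasmid or chromosome) contigs (without a split); `hybrid` — both;
#' `missed` — none of its contigs appear in any unit.
#'
#' @param units Tibble with `unit_id` and `contig_ids` list-column (e.g.
#'   `mob_recon(...)$units`), with pairwise-disjoint contig sets.
#' @param truth_map Tibble from [map_contigs_to_truth()].
#' @param chromosome_ids Replicon ids counted as chromosome.
#' @return A `mob_events` tibble: `plasmid_id`, `event`, `units` (comma
#'   separated unit ids holding its contigs).
#' @export
classify_events <- function(units, truth_map, chromosome_ids = "chromosome") {
  all_ids <- unlist(units$contig_ids)
  if (anyDuplicated(all_ids)) {
    abort(paste0("overlapping units: contigs assigned twice: ",
                 paste(unique(all_ids[duplicated(all_ids)]), collapse = ", ")))
  }
  truth_of <- setNames(truth_map$replicon_id, truth_map$contig_id)
  plasmids <- setdiff(unique(truth_map$replicon_id), chromosome_ids)
  unit_of <- character(0)
  for (i in seq_len(nrow(units))) {
    unit_of[units$contig_ids[[i]]] <- units$unit_id[i]
  }

  rows <- map(plasmids, function(p) {
    own <- truth_map$contig_id[truth_map$replicon_id == p]
    own_units <- unique(unit_of[own])
    own_units <- own_units[!is.na(own_units)]
    if (length(own_units) == 0) {
      return(tibble(plasmid_id = p, event = "missed", units = ""))
    }
    split <- length(own_units) > 1
    merged <- any(map_lgl(own_units, function(u) {
      members <- units$contig_ids[[match(u, units$unit_id)]]
      mapped <- members[members %in% names(truth_of)]
      any(truth_of[mapped] != p)
    }))
    all_in <- all(own %in% names(unit_of) & !is.na(unit_of[own]))
    event <- if (split && merged) "hybrid"
      else if (split) "split"
      else if (merged) "merge"
      else if (all_in) "correct"
      else "split" # some contigs on the chromosome: the plasmid is divided
    tibble(plasmid_id = p, event = event,
           units = paste(sort(own_units), collapse = ","))
  })
  out <- bind_rows(rows)
  class(out) <- c("mob_events", class(out))
  out
}

#' Tabulate reconstruction event counts
#'
#' @param events A `mob_events` tibble from [classify_events()].
#' @return A tibble of counts: plasmids identified (at least one contig in a
#'   unit) and one row per event class.
#' @export
summarize_events <- function(events) {
  n_identified <- sum(events$event != "missed")
  counts <- function(e) sum(events$event == e)
  tibble(
    metric = c("Total plasmids", "Plasmids identified",
               "Correctly partitioned plasmids",
               "Plasmids split across multiple clusters",
               "Plasmids merged into single clusters",
               "Plasmids with a combination of splits and merges",
               "Plasmids missed"),
    count = c(nrow(events), n_identified, counts("correct"), counts("split"),
              counts("merge"), counts("hybrid"), counts("missed"))
  )
}

#' Event-class counts as a bar chart
#'
#' @param object A `mob_events` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mob_events <- function(object, ...) {
  as_tibble(object) |>
    count(.data$event) |>
    mutate(event = factor(.data$event, levels = c("correct", "split", "merge",
                                                  "hybrid", "missed"))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$event, y = .data$n)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::labs(x = NULL, y = "plasmids",
                  title = "Reconstruction event taxonomy") +
    ggplot2::theme_minimal()
}
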