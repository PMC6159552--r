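#' Parse circularity flags from FASTA headers
#'
#' A contig is flagged circular iff its header carries the token
#' `circular=true` (case-insensitive), delimited by whitespace or
#' semicolons.
#'
#' @param x FASTA path or sequence tibble (a `header` column is used when
#'   present, otherwise `id`).
#' @return Tibble with `contig_id` and logical `circular`.
#' @export
parse_circularity <- function(x) {
  tbl <- as_seq_tbl(x)
  headers <- if ("header" %in% names(tbl)) tbl$header else tbl$id
  circ <- map_lgl(headers, function(h) {
    tokens <- tolower(strsplit(h, "[;[:space:]]+")[[1]])
    "circular=true" %in% tokens
  })
  tibble(contig_id = tbl$id, circular = circ)
}

#' Detect overlapping (terminal-repeat) contig ends
#'
#' Returns `TRUE` iff the contig starts and ends with the same exact
#' sequence of at least `min_overlap` bases; the longest candidate overlap
#' (capped at half the contig length) is checked first. This is a
#' conservative stand-in for running an external overlap-based circularizer
#' and is off by default in [mob_recon()].
#'
#' @param sequence A single DNA string.
#' @param min_overlap Minimum exact end-overlap length in bases, default 50.
#' @return Logical scalar.
#' @export
detect_end_overlap <- function(sequence, min_overlap = 50L) {
  n <- nchar(sequence)
  if (n <= 2 * min_overlap) return(FALSE)
  for (len in seq(floor(n / 2), min_overlap)) {
    if (substr(sequence, 1L, len) == substr(sequence, n - len + 1L, n)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Identify candidate plasmid contigs
#'
#' A contig is a candidate iff it carries a replicon hit, a relaxase hit, or
#' is circular. Circular contigs are putative plasmids regardless of any
#' other filter.
#'
#' @param contigs Sequence tibble of the assembly.
#' @param replicon_hits,relaxase_hits Hit tibbles from [mob_search()].
#' @param circular Tibble from [parse_circularity()] (or compatible).
#' @return Tibble with `contig_id` and logical `candidate`.
#' @export
identify_candidates <- function(contigs, replicon_hits, relaxase_hits,
                                circular) {
  tbl <- as_seq_tbl(contigs, arg = "contigs")
  circ <- circular$circular[match(tbl$id, circular$contig_id)]
  circ[is.na(circ)] <- FALSE
  tibble(
    contig_id = tbl$id,
    candidate = tbl$id %in% replicon_hits$contig_id |
      tbl$id %in% relaxase_hits$contig_id | circ
  )
}

#' Flag repeat-dominated contigs
#'
#' A contig is repeat-flagged iff repeat-element hits cover at least
#' `repeat_cov_threshold` of its length (union of hit intervals) and it has
#' neither a replicon nor a relaxase hit. Such contigs are associated with
#' plasmids but are not themselves evidence for one.
#'
#' @inheritParams identify_candidates
#' @param repeat_hits Repeat-element hit tibble.
#' @param repeat_cov_threshold Fraction of contig length, default 0.8.
#' @return Tibble with `contig_id` and logical `repeat_flagged`.
#' @export
flag_repeats <- function(contigs, repeat_hits, replicon_hits, relaxase_hits,
                         repeat_cov_threshold = 0.8) {
  tbl <- as_seq_tbl(contigs, arg = "contigs")
  cov <- map_dbl(seq_len(nrow(tbl)), function(i) {
    h <- repeat_hits[repeat_hits$contig_id == tbl$id[i], , drop = FALSE]
    if (nrow(h) == 0) return(0)
    interval_union_length(h$start, h$end) / nchar(tbl$seq[i])
  })
  tibble(
    contig_id = tbl$id,
    repeat_flagged = cov >= repeat_cov_threshold &
      !(tbl$id %in% replicon_hits$contig_id) &
      !(tbl$id %in% relaxase_hits$contig_id)
  )
}

# Total length covered by a set of half-open intervals.
interval_union_length <- function(start, end) {
  if (length(start) == 0) return(0)
  ord <- order(start)
  start <- start[ord]; end <- end[ord]
  total <- 0; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s)
}

#' Winner-take-all assignment of contigs to reference clusters
#'
#' Every (contig, reference) pair is scored by its cumulative non-overlapping
#' bit score; each reference cluster is ranked by the highest such score
#' among its members (ties: larger summed per-contig best score, then
#' smaller primary id). Walking this priority queue from the top, each
#' still-unassigned contig with any hit to the current cluster joins that
#' cluster's unit, so a contig — including a multi-copy repeat — is assigned
#' to exactly one unit. Candidate contigs (replicon/relaxase/circular) with
#' no reference hit form singleton units; everything else goes to the
#' chromosome. Contigs shorter than `min_contig_length` go to the chromosome
#' unless circular.
#'
#' @param contigs Sequence tibble of the assembly.
#' @param ref_hits Hit tibble against the reference plasmid database
#'   (`subject_type = "plasmid_ref"`).
#' @param ref_codes Tibble mapping `plasmid_id` to `primary_id` (e.g.
#'   `tidy(db)`).
#' @param candidate,circular Tibbles from [identify_candidates()] /
#'   [parse_circularity()].
#' @param min_contig_length Minimum contig length considered, default 500.
#' @return A list: `units` (tibble `unit_key`, `primary_id`, `contig_ids`
#'   list-column) and `contig_map` (tibble `contig_id`, `unit_key`;
#'   `unit_key` is `"chromosome"` for unassigned contigs).
#' @export
assign_contigs <- function(contigs, ref_hits, ref_codes, candidate, circular,
                           min_contig_length = 500L) {
  tbl <- as_seq_tbl(contigs, arg = "contigs")
  circ <- lookup_flag(tbl$id, circular, "circular")
  cand <- lookup_flag(tbl$id, candidate, "candidate")
  eligible <- (nchar(tbl$seq) >= min_contig_length) | circ

  unknown <- setdiff(unique(ref_hits$subject_id), ref_codes$plasmid_id)
  if (length(unknown)) {
    abort(paste0("reference hits name unknown cluster codes for: ",
                 paste(unknown, collapse = ", ")))
  }

  scores <- ref_hits |>
    group_by(.data$contig_id, .data$subject_id) |>
    summarise(
      score = sum(resolve_overlaps(pick("start", "end", "bit_score"),
                                   max_overlap_fraction = 0)$bit_score),
      .groups = "drop"
    ) |>
    left_join(select(ref_codes, "plasmid_id", "primary_id"),
              by = c(subject_id = "plasmid_id"))

  queue <- scores |>
    group_by(.data$contig_id, .data$primary_id) |>
    summarise(best = max(.data$score), .groups = "drop") |>
    group_by(.data$primary_id) |>
    summarise(max_score = max(.data$best), total_score = sum(.data$best),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$max_score), dplyr::desc(.data$total_score),
            .data$primary_id)

  assigned <- setNames(rep(NA_character_, nrow(tbl)), tbl$id)
  for (cl in queue$primary_id) {
    members <- scores$contig_id[scores$primary_id == cl]
    free <- intersect(members, tbl$id[eligible & is.na(assigned[tbl$id])])
    if (length(free)) assigned[free] <- paste0("cluster_", cl)
  }
  # candidates without any reference hit become singleton units
  singles <- tbl$id[eligible & cand & is.na(assigned[tbl$id])]
  assigned[singles] <- paste0("singleton_", singles)
  assigned[is.na(assigned)] <- "chromosome"

  units <- tibble(contig_id = tbl$id, unit_key = unname(assigned[tbl$id])) |>
    filter(.data$unit_key != "chromosome") |>
    group_by(.data$unit_key) |>
    summarise(contig_ids = list(.data$contig_id), .groups = "drop") |>
    mutate(primary_id = {
      pid <- rep(NA_integer_, length(.data$unit_key))
      from_cluster <- grepl("^cluster_", .data$unit_key)
      pid[from_cluster] <-
        as.integer(sub("^cluster_", "", .data$unit_key[from_cluster]))
      pid
    })
  list(units = units,
       contig_map = tibble(contig_id = tbl$id,
                           unit_key = unname(assigned[tbl$id])))
}

lookup_flag <- function(ids, tbl, col) {
  v <- tbl[[col]][match(ids, tbl$contig_id)]
  v[is.na(v)] <- FALSE
  v
}

#' Split circular contigs out of multi-contig units
#'
#' Every circular contig found inside a unit with more than one contig is
#' moved into a fresh singleton unit; single-contig units are unchanged.
#'
#' @param units Unit tibble (`unit_key`, `contig_ids` list-column).
#' @param circular Tibble from [parse_circularity()].
#' @return Updated unit tibble.
#' @export
split_circular_units <- function(units, circular) {
  is_circ <- setNames(circular$circular, circular$contig_id)
  rows <- list()
  for (i in seq_len(nrow(units))) {
    ids <- units$contig_ids[[i]]
    if (length(ids) > 1) {
      circ_ids <- ids[is_circ[ids] %in% TRUE]
      rest <- setdiff(ids, circ_ids)
      for (ci in circ_ids) {
        rows[[length(rows) + 1]] <- units[i, ] |>
          mutate(unit_key = paste0(.data$unit_key, "_circ_", ci),
                 contig_ids = list(ci))
      }
      if (length(rest)) {
        rows[[length(rows) + 1]] <- units[i, ] |>
          mutate(contig_ids = list(rest))
      }
    } else {
      rows[[length(rows) + 1]] <- units[i, ]
    }
  }
  bind_rows(rows)
}

#' Discard repeat-only units
#'
#' A unit whose every contig is repeat-flagged and which contains no
#' replicon or relaxase hit is removed and its contigs reassigned to the
#' chromosome. Units containing a circular contig are exempt.
#'
#' @param units Unit tibble.
#' @param repeat_flagged Tibble from [flag_repeats()].
#' @param replicon_hits,relaxase_hits Hit tibbles.
#' @param circular Tibble from [parse_circularity()].
#' @return A list: `units` (kept units) and `discarded_contigs` (character).
#' @export
discard_repeat_only_units <- function(units, repeat_flagged, replicon_hits,
                                      relaxase_hits, circular) {
  if (nrow(units) == 0) {
    return(list(units = units, discarded_contigs = character(0)))
  }
  flag <- setNames(repeat_flagged$repeat_flagged, repeat_flagged$contig_id)
  is_circ <- setNames(circular$circular, circular$contig_id)
  marker_contigs <- union(replicon_hits$contig_id, relaxase_hits$contig_id)
  drop <- map_lgl(units$contig_ids, function(ids) {
    all(flag[ids] %in% TRUE) &&
      !any(ids %in% marker_contigs) &&
      !any(is_circ[ids] %in% TRUE)
  })
  list(units = units[!drop, , drop = FALSE],
       discarded_contigs = unlist(units$contig_ids[drop]) %||% character(0))
}

#' Label units with their closest reference and novelty status
#'
#' Concatenates each unit's contigs, sketches the result with the database's
#' sketch parameters, and finds the nearest reference plasmid. A unit is
#' novel iff its distance to the closest reference is strictly greater than
#' the loose clustering threshold (default 0.05).
#'
#' @param units Unit tibble.
#' @param contigs Sequence tibble of the assembly.
#' @param db A `mob_db` reference database.
#' @return `units` with `closest_ref`, `closest_distance`, `novel` columns.
#' @export
label_novelty <- function(units, contigs, db) {
  stopifnot(inherits(db, "mob_db"))
  if (length(db$sketches) == 0) abort("reference sketch store is empty")
  tbl <- as_seq_tbl(contigs, arg = "contigs")
  seqs <- setNames(tbl$seq, tbl$id)
  p <- db$params
  res <- map(units$contig_ids, function(ids) {
    sk <- mob_sketch(paste(seqs[ids], collapse = ""), k = p$k, s = p$s,
                     hash_seed = p$hash_seed)
    dists <- map_dbl(db$sketches, ~ mob_distance(sk, .x)$value)
    ord <- order(dists, names(dists))
    list(ref = names(dists)[ord[1]], dist = dists[ord[1]])
  })
  units |>
    mutate(
      closest_ref = map_chr(res, "ref"),
      closest_distance = map_dbl(res, "dist"),
      novel = .data$closest_distance > p$loose_threshold
    )
}

#' Reconstruct plasmid units from a draft assembly
#'
#' The full reconstruction pipeline: circularity parsing (plus optional
#' end-overlap detection), replicon/relaxase/repeat marker searches,
#' candidate identification, repeat flagging, reference search and
#' winner-take-all cluster assignment, circular-unit splitting, repeat-only
#' unit discard, and novelty labelling against the reference database.
#'
#' @param assembly FASTA path or sequence tibble of the draft assembly.
#' @param db A `mob_db` built with [mob_cluster_build()].
#' @param markers Named list of marker databases (FASTA paths or tibbles):
#'   `replicon` and `relaxase` are required; `repeat`, `mpf` and `orit` are
#'   optional.
#' @param min_marker_identity,min_marker_coverage Filters for
#'   replicon/relaxase/mpf/repeat marker hits (percent), default 80/80.
#' @param min_orit_identity,min_orit_coverage Filters for oriT hits,
#'   default 90/90 (short motifs need stricter matching).
#' @param min_ref_identity,min_ref_coverage Filters for reference plasmid
#'   hits (percent; coverage over the contig), default 80/65.
#' @param repeat_cov_threshold Repeat-flagging coverage fraction,
#'   default 0.8.
#' @param min_contig_length Minimum contig length assigned to units (unless
#'   circular), default 500.
#' @param run_end_overlap Also flag contigs with exact overlapping ends as
#'   circular, default `FALSE`.
#' @param min_end_overlap Minimum end overlap in bases, default 50.
#' @param marker_overlap_fraction Overlap tolerance when resolving marker
#'   hits, default 0.1.
#' @return A `mob_recon` object: list with `contigs` (per-contig report
#'   tibble), `units` (unit tibble), `hits` (list of hit tibbles) and
#'   `params`.
#' @export
mob_recon <- function(assembly, db, markers,
                      min_marker_identity = 80, min_marker_coverage = 80,
                      min_orit_identity = 90, min_orit_coverage = 90,
                      min_ref_identity = 80, min_ref_coverage = 65,
                      repeat_cov_threshold = 0.8, min_contig_length = 500L,
                      run_end_overlap = FALSE, min_end_overlap = 50L,
                      marker_overlap_fraction = 0.1) {
  stopifnot(inherits(db, "mob_db"))
  if (!all(c("replicon", "relaxase") %in% names(markers))) {
    abort("markers must include 'replicon' and 'relaxase' databases")
  }
  contigs <- as_seq_tbl(assembly, arg = "assembly")
  circular <- parse_circularity(contigs)
  if (run_end_overlap) {
    eo <- map_lgl(contigs$seq, detect_end_overlap, min_overlap = min_end_overlap)
    circular$circular <- circular$circular | eo
  }

  search_markers <- function(dbx, type, mi, mc) {
    if (is.null(dbx)) return(empty_hits(type))
    mob_search(dbx, contigs, min_identity = mi, min_coverage = mc,
               subject_type = type) |>
      resolve_overlaps(max_overlap_fraction = marker_overlap_fraction)
  }
  replicon_hits <- search_markers(markers$replicon, "replicon",
                                  min_marker_identity, min_marker_coverage)
  relaxase_hits <- search_markers(markers$relaxase, "relaxase",
                                  min_marker_identity, min_marker_coverage)
  repeat_hits <- if (!is.null(markers[["repeat"]])) {
    mob_search(markers[["repeat"]], contigs, min_identity = min_marker_identity,
               min_coverage = min_marker_coverage, subject_type = "repeat")
  } else empty_hits("repeat")
  ref_hits <- mob_search(
    select(db$records, id = "plasmid_id", "seq"), contigs,
    min_identity = min_ref_identity, min_coverage = min_ref_coverage,
    subject_type = "plasmid_ref"
  )

  candidate <- identify_candidates(contigs, replicon_hits, relaxase_hits,
                                   circular)
  repeat_flagged <- flag_repeats(contigs, repeat_hits, replicon_hits,
                                 relaxase_hits, repeat_cov_threshold)

  prelim <- assign_contigs(contigs, ref_hits, tidy(db), candidate, circular,
                           min_contig_length)
  units <- split_circular_units(prelim$units, circular)
  disc <- discard_repeat_only_units(units, repeat_flagged, replicon_hits,
                                    relaxase_hits, circular)
  units <- disc$units

  if (nrow(units) > 0) {
    units <- label_novelty(units, contigs, db)
    units <- finalize_unit_ids(units, db)
    units <- annotate_unit_types(units, replicon_hits, relaxase_hits)
  } else {
    units <- tibble(unit_id = character(), unit_key = character(),
                    primary_id = integer(), contig_ids = list(),
                    closest_ref = character(), closest_distance = numeric(),
                    novel = logical(), cluster_code = character(),
                    replicon_types = character(), relaxase_types = character())
  }

  contig_map <- setNames(rep("chromosome", nrow(contigs)), contigs$id)
  for (i in seq_len(nrow(units))) {
    contig_map[units$contig_ids[[i]]] <- units$unit_id[i]
  }

  best_ref <- ref_hits |>
    group_by(.data$contig_id) |>
    summarise(best_ref_score = max(.data$bit_score), .groups = "drop")

  report <- tibble(
    contig_id = contigs$id,
    length = nchar(contigs$seq),
    circular = circular$circular,
    candidate = candidate$candidate,
    repeat_flagged = repeat_flagged$repeat_flagged,
    assigned_unit = unname(contig_map[contigs$id])
  ) |>
    left_join(units |>
                select("unit_id", "cluster_code", "closest_ref",
                       "closest_distance", "novel"),
              by = c(assigned_unit = "unit_id")) |>
    left_join(best_ref, by = "contig_id") |>
    mutate(
      replicon_hits = hit_families(contigs$id, replicon_hits),
      relaxase_hits = hit_families(contigs$id, relaxase_hits),
      repeat_hits = hit_families(contigs$id, repeat_hits)
    )

  structure(
    list(contigs = report, units = units,
         hits = list(replicon = replicon_hits, relaxase = relaxase_hits,
                     "repeat" = repeat_hits, plasmid_ref = ref_hits),
         discarded_contigs = disc$discarded_contigs,
         params = list(min_marker_identity = min_marker_identity,
                       min_marker_coverage = min_marker_coverage,
                       min_ref_identity = min_ref_identity,
                       min_ref_coverage = min_ref_coverage,
                       repeat_cov_threshold = repeat_cov_threshold,
                       min_contig_length = min_contig_length,
                       loose_threshold = db$params$loose_threshold)),
    class = "mob_recon"
  )
}

# Final unit ids: primary cluster code of the closest reference for known
# units, novel_<n> for novel ones; suffixes keep ids unique.
finalize_unit_ids <- function(units, db) {
  code_of <- setNames(db$records$primary_id, db$records$plasmid_id)
  base <- character(nrow(units))
  novel_n <- 0
  for (i in seq_len(nrow(units))) {
    if (units$novel[i]) {
      novel_n <- novel_n + 1
      base[i] <- paste0("novel_", novel_n)
    } else {
      base[i] <- as.character(code_of[units$closest_ref[i]])
    }
  }
  uniq <- make.unique(base, sep = "_")
  units |>
    mutate(unit_id = uniq,
           cluster_code = ifelse(.data$novel, NA_character_, base))
}

annotate_unit_types <- function(units, replicon_hits, relaxase_hits) {
  units |>
    mutate(
      replicon_types = map_chr(.data$contig_ids, function(ids) {
        collapse_families(replicon_hits$subject_id[replicon_hits$contig_id %in% ids])
      }),
      relaxase_types = map_chr(.data$contig_ids, function(ids) {
        collapse_families(relaxase_hits$subject_id[relaxase_hits$contig_id %in% ids])
      }),
      n_contigs = lengths(.data$contig_ids)
    )
}

# Marker family = subject id prefix before the first underscore.
marker_family <- function(subject_id) sub("_.*$", "", subject_id)

collapse_families <- function(subject_ids) {
  if (length(subject_ids) == 0) return("-")
  paste(sort(unique(marker_family(subject_ids))), collapse = ",")
}

hit_families <- function(ids, hits) {
  map_chr(ids, function(id) {
    collapse_families(hits$subject_id[hits$contig_id == id])
  })
}

empty_hits <- function(type) {
  tibble(contig_id = character(), subject_id = character(),
         subject_type = character(), pct_identity = numeric(),
         subject_coverage = numeric(), query_coverage = numeric(),
         bit_score = numeric(), start = integer(), end = integer(),
         strand = character(), length = integer())
}

#' @export
print.mob_recon <- function(x, ...) {
  cat("<mob_recon>", nrow(x$units), "plasmid units from",
      nrow(x$contigs), "contigs;",
      sum(x$contigs$assigned_unit == "chromosome"), "contigs on chromosome\n")
  invisible(x)
}

#' @describeIn mob_recon Per-contig report tibble.
#' @param x,object A `mob_recon` object.
#' @param ... Unused.
#' @export
tidy.mob_recon <- function(x, ...) x$contigs

#' @describeIn mob_recon One-row reconstruction summary.
#' @export
glance.mob_recon <- function(x, ...) {
  tibble(
    n_contigs = nrow(x$contigs),
    n_units = nrow(x$units),
    n_novel = sum(x$units$novel),
    n_chromosome = sum(x$contigs$assigned_unit == "chromosome"),
    plasmid_bases = sum(x$contigs$length[x$contigs$assigned_unit != "chromosome"]),
    chromosome_bases = sum(x$contigs$length[x$contigs$assigned_unit == "chromosome"])
  )
}

#' @describeIn mob_recon Bases assigned per unit, coloured by novelty.
#' @export
autoplot.mob_recon <- function(object, ...) {
  tidy(object) |>
    mutate(unit = .data$assigned_unit) |>
    group_by(.data$unit) |>
    summarise(bases = sum(.data$length),
              novel = any(.data$novel %in% TRUE), .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(x = stats::reorder(.data$unit, -.data$bases),
                                 y = .data$bases, fill = .data$novel)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "bases",
                  title = "Bases per reconstructed unit") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write reconstruction outputs to a directory
#'
#' Writes one FASTA per plasmid unit (`plasmid_<unit_id>.fasta`),
#' `chromosome.fasta` with all chromosome-assigned contigs, and
#' `contig_report.tsv` with one row per contig.
#'
#' @param res A `mob_recon` object.
#' @param assembly The assembly used for reconstruction (path or tibble).
#' @param outdir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_recon_outputs <- function(res, assembly, outdir) {
  stopifnot(inherits(res, "mob_recon"))
  contigs <- as_seq_tbl(assembly, arg = "assembly")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) abort(paste0("cannot create output dir: ", outdir))
  paths <- character(0)
  for (i in seq_len(nrow(res$units))) {
    ids <- res$units$contig_ids[[i]]
    p <- file.path(outdir, paste0("plasmid_", res$units$unit_id[i], ".fasta"))
    write_fasta(contigs[match(ids, contigs$id), ], p)
    paths <- c(paths, p)
  }
  chrom_ids <- res$contigs$contig_id[res$contigs$assigned_unit == "chromosome"]
  chrom_path <- file.path(outdir, "chromosome.fasta")
  if (length(chrom_ids)) {
    write_fasta(contigs[match(chrom_ids, contigs$id), ], chrom_path)
  } else {
    writeLines(character(0), chrom_path)
  }
  report_path <- file.path(outdir, "contig_report.tsv")
  readr::write_tsv(res$contigs, report_path)
  invisible(c(paths, chrom_path, report_path))
}
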