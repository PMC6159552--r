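#' Search a marker or reference database against assembly contigs
#'
#' Runs the bundled ungapped seed-and-extend aligner (exact seed-word
#' anchoring plus maximal-scoring-segment extension along each anchored
#' diagonal; blastn-style bit scores) and filters hits for identity and
#' coverage. Hit coordinates are normalised to the forward strand of the
#' contig as 0-based half-open intervals.
#'
#' Coverage is computed over the subject (marker) length when
#' `coverage_on = "subject"` — appropriate for short markers searched against
#' long contigs. With `coverage_on = "query"` (the default for
#' `subject_type = "plasmid_ref"`), hits are aggregated per
#' (contig, subject): non-overlapping HSPs are combined, coverage is the
#' combined fraction of the contig aligned, and the identity filter applies
#' to the length-weighted mean identity of the combination.
#'
#' @param database FASTA path or tibble of subject (marker/reference)
#'   sequences.
#' @param assembly FASTA path or tibble of contigs.
#' @param min_identity Minimum percent identity, default 80.
#' @param min_coverage Minimum percent coverage (see `coverage_on`),
#'   default 80.
#' @param subject_type One of `"replicon"`, `"relaxase"`, `"mpf"`, `"orit"`,
#'   `"repeat"`, `"plasmid_ref"`; recorded on each hit.
#' @param coverage_on `"subject"` or `"query"`.
#' @param seed_len Exact seed-word length of the aligner, default 15.
#' @param min_raw Minimum raw segment score retained, default 30.
#' @return A tibble of hits: `contig_id`, `subject_id`, `subject_type`,
#'   `pct_identity`, `subject_coverage`, `query_coverage`, `bit_score`,
#'   `start`, `end` (contig interval), `strand`, `length`.
#' @export
mob_search <- function(database, assembly, min_identity = 80,
                       min_coverage = 80, subject_type = "replicon",
                       coverage_on = if (subject_type == "plasmid_ref")
                         "query" else "subject",
                       seed_len = 15L, min_raw = 30) {
  coverage_on <- match.arg(coverage_on, c("subject", "query"))
  subjects <- as_seq_tbl(database, arg = "database")
  contigs <- as_seq_tbl(assembly, arg = "assembly")
  if (nrow(subjects) == 0 || nrow(contigs) == 0) {
    abort("empty database or assembly")
  }

  raw <- .seed_search_cpp(contigs$id, contigs$seq, subjects$id, subjects$seq,
                          as.integer(seed_len), 2, 3, min_raw, 0.625, 0.41)
  hits <- as_tibble(raw) |>
    mutate(
      contig_id = as.character(.data$contig_id),
      subject_id = as.character(.data$subject_id),
      subject_type = subject_type,
      subject_len = nchar(subjects$seq)[match(.data$subject_id, subjects$id)],
      contig_len = nchar(contigs$seq)[match(.data$contig_id, contigs$id)],
      subject_coverage = 100 * .data$length / .data$subject_len,
      query_coverage = 100 * .data$length / .data$contig_len
    )

  if (coverage_on == "subject") {
    out <- filter(hits, .data$pct_identity >= min_identity,
                  .data$subject_coverage >= min_coverage)
  } else {
    # combine HSPs per (contig, subject); keep groups passing the combined
    # coverage and weighted-identity filters
    keep <- hits |>
      group_by(.data$contig_id, .data$subject_id) |>
      group_modify(function(g, key) {
        surv <- resolve_overlaps(g, max_overlap_fraction = 0)
        tibble(
          comb_cov = 100 * sum(surv$length) / g$contig_len[1],
          comb_ident = sum(surv$pct_identity * surv$length) / sum(surv$length)
        )
      }) |>
      ungroup() |>
      filter(.data$comb_ident >= min_identity, .data$comb_cov >= min_coverage)
    out <- semi_join(hits, keep, by = c("contig_id", "subject_id"))
  }
  out |>
    select("contig_id", "subject_id", "subject_type", "pct_identity",
           "subject_coverage", "query_coverage", "bit_score", "start", "end",
           "strand", "length") |>
    arrange(.data$contig_id, dplyr::desc(.data$bit_score), .data$subject_id,
            .data$start)
}

#' Greedy resolution of overlapping hits
#'
#' Hits are taken in order of decreasing bit score (ties: longer interval,
#' then lexicographically smaller subject id, then smaller start). A hit is
#' accepted iff its contig interval overlaps each previously accepted
#' interval on the same contig by at most `max_overlap_fraction` of the
#' shorter of the two intervals. With the default cap of 0 the accepted set
#' is strictly non-overlapping.
#'
#' @param hits Tibble of hits with at least `contig_id`, `bit_score`,
#'   `start`, `end`.
#' @param max_overlap_fraction Allowed pairwise overlap as a fraction of the
#'   shorter interval, in \[0, 1\]. Default 0.
#' @return The accepted subset, in acceptance order within each contig.
#' @export
resolve_overlaps <- function(hits, max_overlap_fraction = 0) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0) return(hits)
  len <- hits$end - hits$start
  n <- nrow(hits)
  sid <- if ("subject_id" %in% names(hits)) hits$subject_id else rep("", n)
  ord <- order(-hits$bit_score, -len, sid, hits$start)
  out_idx <- integer(0)
  split_by <- if ("contig_id" %in% names(hits)) hits$contig_id else rep("", n)
  for (cid in unique(split_by)) {
    accepted <- integer(0)
    for (i in ord[split_by[ord] == cid]) {
      ok <- TRUE
      for (j in accepted) {
        ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
        shorter <- min(len[i], len[j])
        if (ov > max_overlap_fraction * shorter) { ok <- FALSE; break }
      }
      if (ok) accepted <- c(accepted, i)
    }
    out_idx <- c(out_idx, accepted)
  }
  hits[out_idx, , drop = FALSE]
}

#' Cumulative non-overlapping bit score
#'
#' The score of a contig against one reference: hits are reduced to a
#' strictly non-overlapping set by greedy best-bit-score selection
#' ([resolve_overlaps()] with cap 0) and the surviving bit scores are summed.
#' The result does not depend on the input hit order.
#'
#' @param hits Tibble of hits sharing one `contig_id` and one `subject_id`.
#' @return A single numeric score (0 for an empty hit set).
#' @export
cumulative_bitscore <- function(hits) {
  if (nrow(hits) == 0) return(0)
  if (n_distinct(hits$contig_id) > 1 || n_distinct(hits$subject_id) > 1) {
    abort("hits must share one contig_id and one subject_id")
  }
  sum(resolve_overlaps(hits, max_overlap_fraction = 0)$bit_score)
}

#' Search backend based on command-line blastn
#'
#' Optional external backend with the same contract as [mob_search()] for
#' `coverage_on = "subject"`; used to cross-check the bundled aligner.
#' Requires `makeblastdb` and `blastn` on the PATH.
#'
#' @inheritParams mob_search
#' @return A tibble with the [mob_search()] hit columns.
#' @export
mob_search_blast <- function(database, assembly, min_identity = 80,
                             min_coverage = 80, subject_type = "replicon") {
  if (Sys.which("blastn") == "" || Sys.which("makeblastdb") == "") {
    abort("blastn/makeblastdb not found on PATH")
  }
  subjects <- as_seq_tbl(database, arg = "database")
  contigs <- as_seq_tbl(assembly, arg = "assembly")
  td <- tempfile("blast"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  dbfa <- file.path(td, "contigs.fasta"); qfa <- file.path(td, "subjects.fasta")
  write_fasta(contigs, dbfa)
  write_fasta(subjects, qfa)
  system2("makeblastdb", c("-in", dbfa, "-dbtype", "nucl"),
          stdout = FALSE, stderr = FALSE)
  out <- file.path(td, "hits.tsv")
  system2("blastn", c("-query", qfa, "-db", dbfa, "-out", out,
                      "-outfmt", shQuote(paste("6 qseqid sseqid pident length",
                                               "bitscore qstart qend sstart",
                                               "send")),
                      "-dust", "no"),
          stdout = FALSE, stderr = FALSE)
  cols <- c("subject_id", "contig_id", "pct_identity", "length", "bit_score",
            "qstart", "qend", "sstart", "send")
  if (!file.exists(out) || file.size(out) == 0) {
    hits <- tibble(subject_id = character(), contig_id = character(),
                   pct_identity = numeric(), length = integer(),
                   bit_score = numeric(), qstart = integer(), qend = integer(),
                   sstart = integer(), send = integer())
  } else {
    hits <- readr::read_tsv(out, col_names = cols, show_col_types = FALSE)
  }
  hits |>
    mutate(
      subject_id = as.character(.data$subject_id),
      contig_id = as.character(.data$contig_id),
      subject_type = subject_type,
      subject_len = nchar(subjects$seq)[match(.data$subject_id, subjects$id)],
      contig_len = nchar(contigs$seq)[match(.data$contig_id, contigs$id)],
      subject_coverage = 100 * .data$length / .data$subject_len,
      query_coverage = 100 * .data$length / .data$contig_len,
      strand = ifelse(.data$send >= .data$sstart, "+", "-"),
      start = pmin(.data$sstart, .data$send) - 1L,
      end = pmax(.data$sstart, .data$send)
    ) |>
    filter(.data$pct_identity >= min_identity,
           .data$subject_coverage >= min_coverage) |>
    select("contig_id", "subject_id", "subject_type", "pct_identity",
           "subject_coverage", "query_coverage", "bit_score", "start", "end",
           "strand", "length") |>
    arrange(.data$contig_id, dplyr::desc(.data$bit_score), .data$subject_id,
            .data$start)
}
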