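#' Pairwise genomic distances for a reference plasmid set
#'
#' Sketches every record and computes the full symmetric MinHash distance
#' matrix used for cluster-code assignment.
#'
#' @param plasmids A FASTA path or tibble with `plasmid_id`/`id` and
#'   `seq`/`sequence` columns; ids must be unique.
#' @inheritParams mob_sketch
#' @return Symmetric distance matrix (zero diagonal) with plasmid ids as
#'   dimnames.
#' @export
mob_pairwise_distances <- function(plasmids, k = 21L, s = 1000L,
                                   hash_seed = 42L) {
  tbl <- as_seq_tbl(plasmids, arg = "plasmids")
  if (nrow(tbl) < 1) abort("need at least one record")
  mob_distance_matrix(tbl, k = k, s = s, hash_seed = hash_seed)
}

#' Single-linkage flat clustering at a distance threshold
#'
#' Two records fall in the same cluster iff they are connected in the graph
#' whose edges are record pairs at distance <= `threshold` (single-linkage
#' flat clusters are exactly the connected components of the threshold
#' graph). Uses [stats::hclust()] with `method = "single"` cut at height
#' `threshold`. Labels are positive integers in order of first appearance of
#' each cluster in the input.
#'
#' @param d Symmetric distance matrix with dimnames, zero diagonal.
#' @param threshold Distance threshold in \[0, 1\].
#' @return Named integer vector: record id -> cluster label.
#' @export
mob_single_linkage <- function(d, threshold) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (threshold < 0 || threshold > 1) abort("threshold must be in [0, 1]")
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  if (nrow(d) == 1) return(setNames(1L, ids))
  tree <- hclust(as.dist(d), method = "single")
  raw <- cutree(tree, h = threshold)
  relabel_first_appearance(setNames(as.integer(raw), ids))
}

# Renumber cluster labels 1..K by order of first appearance.
relabel_first_appearance <- function(labels) {
  first <- labels[!duplicated(labels)]
  setNames(match(labels, first), names(labels))
}

#' Build a clustered reference plasmid database
#'
#' Computes pairwise MinHash distances, performs single-linkage clustering at
#' a loose and a strict threshold, and assigns each plasmid a nested cluster
#' code `primary.secondary`. The strict-level partition always refines the
#' loose-level one, so records sharing a secondary id share the primary id.
#' Default thresholds (0.05, 0.001) follow the published defaults, which were
#' tuned on Enterobacteriaceae plasmids.
#'
#' @param plasmids A FASTA path or tibble with plasmid ids and sequences.
#' @param loose_threshold Distance threshold of the primary (loose) level.
#' @param strict_threshold Distance threshold of the secondary (strict)
#'   level; must be <= `loose_threshold`.
#' @param min_length Optional minimum plasmid length in bases; records below
#'   it are rejected with an error. `NULL` (default) disables the filter.
#' @inheritParams mob_sketch
#' @return A `mob_db` object: list with `records` (tibble of plasmid_id,
#'   length, primary_id, secondary_id, cluster_code, seq), `sketches`,
#'   `params` and id `counters`.
#' @examples
#' refs <- tibble::tibble(
#'   plasmid_id = c("p1", "p2"),
#'   seq = replicate(2, paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
#'                            collapse = ""))
#' )
#' db <- mob_cluster_build(refs)
#' tidy(db)
#' @export
mob_cluster_build <- function(plasmids, loose_threshold = 0.05,
                              strict_threshold = 0.001,
                              min_length = NULL,
                              k = 21L, s = 1000L, hash_seed = 42L) {
  if (strict_threshold > loose_threshold) {
    abort("strict_threshold must be <= loose_threshold")
  }
  tbl <- as_seq_tbl(plasmids, arg = "plasmids")
  if (!is.null(min_length)) {
    short <- tbl$id[nchar(tbl$seq) < min_length]
    if (length(short)) {
      abort(paste0("records below min_length: ", paste(short, collapse = ", ")))
    }
  }
  sketches <- mob_sketch_set(tbl, k = k, s = s, hash_seed = hash_seed)
  d <- mob_distance_matrix(sketches)
  primary <- mob_single_linkage(d, loose_threshold)
  secondary <- mob_single_linkage(d, strict_threshold)

  records <- tibble(
    plasmid_id = tbl$id,
    length = nchar(tbl$seq),
    primary_id = as.integer(primary[tbl$id]),
    secondary_id = as.integer(secondary[tbl$id]),
    seq = tbl$seq
  ) |>
    mutate(cluster_code = paste0(.data$primary_id, ".", .data$secondary_id),
           .after = "secondary_id")

  structure(
    list(
      records = records,
      sketches = sketches,
      params = list(loose_threshold = loose_threshold,
                    strict_threshold = strict_threshold,
                    k = as.integer(k), s = as.integer(s),
                    hash_seed = as.integer(hash_seed)),
      counters = list(primary = max(records$primary_id),
                      secondary = max(records$secondary_id))
    ),
    class = "mob_db"
  )
}

#' @export
print.mob_db <- function(x, ...) {
  cat("<mob_db>", nrow(x$records), "reference plasmids,",
      x$counters$primary, "primary /", x$counters$secondary,
      "secondary clusters\n")
  cat("  thresholds:", x$params$loose_threshold, "/",
      x$params$strict_threshold,
      " sketch: k =", x$params$k, ", s =", x$params$s, "\n")
  invisible(x)
}

#' @describeIn mob_cluster_build Tidy the database records (one row per
#'   plasmid, without sequences).
#' @param x A `mob_db` object.
#' @param ... Unused.
#' @export
tidy.mob_db <- function(x, ...) {
  select(x$records, -"seq")
}

#' @describeIn mob_cluster_build One-row database summary.
#' @export
glance.mob_db <- function(x, ...) {
  tibble(
    n_plasmids = nrow(x$records),
    n_primary = n_distinct(x$records$primary_id),
    n_secondary = n_distinct(x$records$secondary_id),
    loose_threshold = x$params$loose_threshold,
    strict_threshold = x$params$strict_threshold
  )
}

#' Incrementally add plasmids to a clustered database
#'
#' New records are processed in input order. A record whose nearest database
#' member lies within the strict threshold inherits that member's full
#' cluster code; within the loose threshold only, it inherits the primary id
#' and receives a fresh secondary id; outside both, it receives fresh primary
#' and secondary ids. Fresh ids come from monotone counters and are never
#' reused, and codes of pre-existing records are never changed, so cluster
#' designations remain stable across database updates.
#'
#' If a new record lies within the loose threshold of more than one existing
#' primary cluster (a bridge), it joins the cluster of its nearest member
#' (ties: smaller primary id, then lexicographically smaller plasmid id);
#' existing clusters are not merged and a warning reports the bridge.
#'
#' @param db A `mob_db` from [mob_cluster_build()].
#' @param new_plasmids FASTA path or tibble of new records; ids must not
#'   already exist in the database.
#' @return The updated `mob_db`.
#' @export
mob_cluster_update <- function(db, new_plasmids) {
  stopifnot(inherits(db, "mob_db"))
  tbl <- as_seq_tbl(new_plasmids, arg = "new_plasmids")
  dup <- intersect(tbl$id, db$records$plasmid_id)
  if (length(dup)) {
    abort(paste0("duplicate plasmid_id: ", paste(dup, collapse = ", ")))
  }
  p <- db$params
  for (i in seq_len(nrow(tbl))) {
    id <- tbl$id[i]
    sk <- mob_sketch(tbl$seq[i], k = p$k, s = p$s, hash_seed = p$hash_seed,
                     sequence_id = id)
    dists <- map_dbl(db$sketches, ~ mob_distance(sk, .x)$value)
    cand <- tibble(
      plasmid_id = names(dists),
      distance = unname(dists)
    ) |>
      left_join(select(db$records, "plasmid_id", "primary_id", "secondary_id"),
                by = "plasmid_id") |>
      arrange(.data$distance, .data$primary_id, .data$plasmid_id)

    within_loose <- filter(cand, .data$distance <= p$loose_threshold)
    bridged <- n_distinct(within_loose$primary_id) > 1
    if (bridged) {
      warn(paste0("record '", id, "' bridges primary clusters ",
                  paste(sort(unique(within_loose$primary_id)), collapse = ", "),
                  "; joining the nearest, existing codes unchanged"))
    }
    nearest <- cand[1, ]
    if (nrow(cand) > 0 && nearest$distance <= p$strict_threshold) {
      primary_id <- nearest$primary_id
      secondary_id <- nearest$secondary_id
    } else if (nrow(cand) > 0 && nearest$distance <= p$loose_threshold) {
      primary_id <- nearest$primary_id
      secondary_id <- db$counters$secondary <- db$counters$secondary + 1L
    } else {
      primary_id <- db$counters$primary <- db$counters$primary + 1L
      secondary_id <- db$counters$secondary <- db$counters$secondary + 1L
    }
    db$records <- bind_rows(db$records, tibble(
      plasmid_id = id, length = nchar(tbl$seq[i]),
      primary_id = as.integer(primary_id),
      secondary_id = as.integer(secondary_id),
      cluster_code = paste0(primary_id, ".", secondary_id),
      seq = tbl$seq[i]
    ))
    db$sketches[[id]] <- sk
  }
  db
}

#' Write a clustered database to a directory
#'
#' Writes `refs.fasta` (headers `plasmid_id|cluster=P.S`), a `db.tsv`
#' sidecar, the sketch file `sketches.json` and `params.json`.
#'
#' @param db A `mob_db`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mob_db <- function(db, dir) {
  stopifnot(inherits(db, "mob_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- db$records |>
    mutate(header = paste0(.data$plasmid_id, "|cluster=", .data$cluster_code)) |>
    select(id = "plasmid_id", "seq", "header")
  write_fasta(fa, file.path(dir, "refs.fasta"))
  readr::write_tsv(select(db$records, -"seq"), file.path(dir, "db.tsv"))
  write_sketch_db(db$sketches, file.path(dir, "sketches.json"))
  jsonlite::write_json(c(db$params, db$counters["primary"],
                         list(secondary_counter = db$counters$secondary)),
                       file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a clustered database written by [write_mob_db()]
#'
#' @param dir Database directory.
#' @return A `mob_db`.
#' @export
read_mob_db <- function(dir) {
  tsv <- file.path(dir, "db.tsv")
  if (!file.exists(tsv)) abort(paste0("not a mobkit database directory: ", dir))
  records <- readr::read_tsv(tsv, show_col_types = FALSE) |>
    mutate(plasmid_id = as.character(.data$plasmid_id),
           cluster_code = as.character(.data$cluster_code))
  fa <- read_fasta(file.path(dir, "refs.fasta"))
  records$seq <- fa$seq[match(records$plasmid_id, sub("\\|.*$", "", fa$id))]
  pj <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  structure(
    list(
      records = as_tibble(records),
      sketches = read_sketch_db(file.path(dir, "sketches.json")),
      params = list(loose_threshold = pj$loose_threshold,
                    strict_threshold = pj$strict_threshold,
                    k = as.integer(pj$k), s = as.integer(pj$s),
                    hash_seed = as.integer(pj$hash_seed)),
      counters = list(primary = as.integer(pj$primary),
                      secondary = as.integer(pj$secondary_counter))
    ),
    class = "mob_db"
  )
}

#' Bar chart of primary cluster sizes
#'
#' @param object A `mob_db`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mob_db <- function(object, ...) {
  tidy(object) |>
    count(.data$primary_id) |>
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$primary_id), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "primary cluster", y = "plasmids",
                  title = "Reference plasmids per primary cluster") +
    ggplot2::theme_minimal()
}
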