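#' Build a bottom-s MinHash sketch of a DNA sequence
#'
#' Hashes every canonical k-mer (the lexicographic minimum of a k-mer and its
#' reverse complement) with a seeded 64-bit mixing function and keeps the `s`
#' numerically smallest distinct values. Two sketches built with the same
#' `k`, `s` and `hash_seed` can be compared with [mob_distance()] to estimate
#' the genomic (substitution) distance between the underlying sequences.
#'
#' k-mers containing any non-ACGT base (e.g. N) are skipped. Hash values are
#' truncated to 53 bits so they are exactly representable as R doubles.
#'
#' @param sequence A DNA string (A/C/G/T/N), length >= `k`.
#' @param k K-mer length, default 21.
#' @param s Sketch size (number of hashes retained), default 1000.
#' @param hash_seed Integer seed of the hash function; sketches are only
#'   comparable when built with the same seed. Default 42.
#' @param sequence_id Optional identifier stored in the sketch.
#' @return An object of class `mob_sketch`: a list with elements
#'   `sequence_id`, `k`, `s`, `hash_seed` and `hashes` (strictly increasing
#'   numeric vector of at most `s` values).
#' @examples
#' sk <- mob_sketch(paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""))
#' length(sk$hashes)
#' @export
mob_sketch <- function(sequence, k = 21L, s = 1000L, hash_seed = 42L,
                       sequence_id = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!nzchar(sequence) || nchar(sequence) < k) {
    abort("sequence too short")
  }
  hashes <- .sketch_cpp(sequence, as.integer(k), as.integer(s),
                        as.double(hash_seed))
  structure(
    list(sequence_id = sequence_id, k = as.integer(k), s = as.integer(s),
         hash_seed = as.integer(hash_seed), hashes = hashes),
    class = "mob_sketch"
  )
}

#' @export
print.mob_sketch <- function(x, ...) {
  cat("<mob_sketch", if (!is.null(x$sequence_id)) paste0("'", x$sequence_id, "'"),
      "k =", x$k, "s =", x$s, "|", length(x$hashes), "hashes>\n")
  invisible(x)
}

#' Sketch every sequence of a table
#'
#' @param x A FASTA path or a tibble with id and seq/sequence columns.
#' @inheritParams mob_sketch
#' @return A named list of [mob_sketch()] objects, one per record.
#' @export
mob_sketch_set <- function(x, k = 21L, s = 1000L, hash_seed = 42L) {
  tbl <- as_seq_tbl(x)
  out <- map2(tbl$seq, tbl$id, function(sq, id) {
    tryCatch(
      mob_sketch(sq, k = k, s = s, hash_seed = hash_seed, sequence_id = id),
      error = function(e) abort(paste0("record '", id, "': ", conditionMessage(e)))
    )
  })
  setNames(out, tbl$id)
}

#' MinHash genomic distance between two sketches
#'
#' Estimates the Jaccard index from the merged bottom-s sketch (the `s`
#' smallest values of the union of both hash sets) and converts it to a
#' genomic distance with the Poisson k-mer-survival model
#' \eqn{d = -\frac{1}{k}\ln\frac{2j}{1+j}}, capped to \[0, 1\]. `d = 1` when
#' the sketches share no hashes and exactly 0 for identical sketches.
#'
#' @param a,b `mob_sketch` objects built with identical `k`, `s` and hash seed.
#' @return A one-row tibble: `value` (the distance), `jaccard`, `shared`
#'   (shared bottom hashes) and `denominator` (merged bottom hashes used).
#' @examples
#' s1 <- mob_sketch(strrep("ACGTT", 200))
#' mob_distance(s1, s1)$value
#' @export
mob_distance <- function(a, b) {
  stopifnot(inherits(a, "mob_sketch"), inherits(b, "mob_sketch"))
  if (a$k != b$k || a$s != b$s || a$hash_seed != b$hash_seed) {
    abort("incompatible sketches")
  }
  est <- .mash_jaccard(a$hashes, b$hashes, a$s)
  tibble(
    value = mash_distance_from_jaccard(est$jaccard, a$k),
    jaccard = est$jaccard,
    shared = est$shared,
    denominator = est$denominator
  )
}

# Merged bottom-s Jaccard estimate from two sorted hash vectors.
.mash_jaccard <- function(ha, hb, s) {
  merged <- sort(unique(c(ha, hb)))
  n <- min(s, length(merged))
  bottom <- merged[seq_len(n)]
  shared <- sum(bottom %in% ha & bottom %in% hb)
  list(jaccard = shared / n, shared = shared, denominator = n)
}

#' Convert a Jaccard estimate to a MinHash genomic distance
#'
#' @param j Jaccard index in \[0, 1\].
#' @param k K-mer length used for sketching.
#' @return Distance in \[0, 1\]; 1 when `j = 0`, 0 when `j = 1`.
#' @export
mash_distance_from_jaccard <- function(j, k) {
  stopifnot(all(j >= 0 & j <= 1))
  d <- ifelse(j == 0, 1, pmin(1, pmax(0, -(1 / k) * log(2 * j / (1 + j)))))
  d[j == 1] <- 0
  d
}

#' Pairwise MinHash distance matrix
#'
#' @param x A FASTA path, a sequence tibble, or a named list of sketches
#'   from [mob_sketch_set()].
#' @inheritParams mob_sketch
#' @return A symmetric numeric matrix with zero diagonal, dimnames set to
#'   record ids.
#' @export
mob_distance_matrix <- function(x, k = 21L, s = 1000L, hash_seed = 42L) {
  sketches <- if (is.list(x) && all(map_chr(x, ~class(.x)[1]) == "mob_sketch")) {
    x
  } else {
    mob_sketch_set(x, k = k, s = s, hash_seed = hash_seed)
  }
  n <- length(sketches)
  ids <- names(sketches)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d <- mob_distance(sketches[[i]], sketches[[j]])$value
        m[i, j] <- d
        m[j, i] <- d
      }
    }
  }
  m
}

#' Write a sketch set to a versioned JSON file
#'
#' @param sketches Named list of `mob_sketch` objects sharing `k`, `s` and
#'   hash seed.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sketch_db <- function(sketches, path) {
  stopifnot(length(sketches) > 0)
  k <- sketches[[1]]$k; s <- sketches[[1]]$s; seed <- sketches[[1]]$hash_seed
  obj <- list(
    format = "mobkit-sketch", version = 1L,
    k = k, s = s, hash_seed = seed,
    # 53-bit hash values serialised as decimal strings so no precision is
    # lost through the JSON number formatter
    records = map(sketches, ~ sprintf("%.0f", .x$hashes))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sketch set written by [write_sketch_db()]
#'
#' @param path JSON sketch file.
#' @return Named list of `mob_sketch` objects.
#' @export
read_sketch_db <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mobkit-sketch")) {
    abort(paste0("not a mobkit sketch file: ", path))
  }
  imap(obj$records, function(h, id) {
    structure(
      list(sequence_id = id, k = as.integer(obj$k), s = as.integer(obj$s),
           hash_seed = as.integer(obj$hash_seed), hashes = as.numeric(h)),
      class = "mob_sketch"
    )
  })
}

#' Count distinct canonical k-mers of a sequence
#'
#' Exact enumeration; intended for short sequences and for validating
#' sketches against exact Jaccard values.
#'
#' @inheritParams mob_sketch
#' @return Integer count.
#' @export
count_canonical_kmers <- function(sequence, k = 21L) {
  .count_canonical_kmers_cpp(sequence, as.integer(k))
}
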