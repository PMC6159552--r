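test_that("circularity tokens are parsed case-insensitively", {
  tbl <- tibble::tibble(
    id = c("c1", "c2", "c3"),
    header = c("c1 circular=true", "c2", "c3 Circular=TRUE;cov=30"),
    seq = strrep("ACGT", 30)
  )
  flags <- parse_circularity(tbl)
  expect_equal(flags$circular, c(TRUE, FALSE, TRUE))
  # the token must be delimited, not a substring of another word
  tbl2 <- tibble::tibble(id = "c4", header = "c4 noncircular=trueish",
                         seq = strrep("ACGT", 30))
  expect_false(parse_circularity(tbl2)$circular)
})

test_that("end overlaps are detected only above the cutoff", {
  set.seed(41)
  s <- random_dna(3000)
  expect_true(detect_end_overlap(paste0(s, substr(s, 1, 100)),
                                 min_overlap = 50))
  expect_false(detect_end_overlap(paste0(s, substr(s, 1, 30)),
                                  min_overlap = 50))
  expect_false(detect_end_overlap(random_dna(3000), min_overlap = 50))
})

test_that("candidate contigs are replicon/relaxase carriers or circular", {
  contigs <- tibble::tibble(id = c("a", "b", "c", "d"),
                            seq = strrep("ACGT", 200))
  rep_hits <- tibble::tibble(contig_id = "a")
  rel_hits <- tibble::tibble(contig_id = character(0))
  circ <- tibble::tibble(contig_id = c("a", "b", "c", "d"),
                         circular = c(FALSE, TRUE, FALSE, FALSE))
  cand <- identify_candidates(contigs, rep_hits, rel_hits, circ)
  expect_equal(cand$candidate, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("repeat flagging needs high coverage and no markers", {
  contigs <- tibble::tibble(id = c("is1", "withrep", "low"),
                            seq = c(strrep("A", 1000), strrep("A", 1000),
                                    strrep("A", 1000)))
  repeat_hits <- tibble::tibble(
    contig_id = c("is1", "withrep", "low"),
    start = c(0, 0, 0), end = c(1000, 1000, 100)
  )
  rep_hits <- tibble::tibble(contig_id = "withrep")
  rel_hits <- tibble::tibble(contig_id = character(0))
  flags <- flag_repeats(contigs, repeat_hits, rep_hits, rel_hits, 0.8)
  expect_equal(flags$repeat_flagged, c(TRUE, FALSE, FALSE))
})

test_that("winner-take-all assignment follows the cluster priority queue", {
  contigs <- tibble::tibble(id = c("c1", "c2", "c3"),
                            seq = strrep("ACGT", 300))
  ref_codes <- tibble::tibble(plasmid_id = c("r3", "r7"),
                              primary_id = c(3L, 7L))
  hits <- tibble::tibble(
    contig_id = c("c1", "c1", "c2"),
    subject_id = c("r3", "r7", "r7"),
    bit_score = c(900, 400, 400),
    start = c(0, 0, 0), end = c(500, 300, 300)
  )
  circ <- tibble::tibble(contig_id = contigs$id, circular = FALSE)
  cand <- tibble::tibble(contig_id = contigs$id, candidate = FALSE)
  out <- assign_contigs(contigs, hits, ref_codes, cand, circ)
  map <- setNames(out$contig_map$unit_key, out$contig_map$contig_id)
  expect_equal(unname(map["c1"]), "cluster_3")   # highest-ranking cluster
  expect_equal(unname(map["c2"]), "cluster_7")
  expect_equal(unname(map["c3"]), "chromosome")  # no hit, not candidate
})

test_that("a shared contig joins exactly one unit under ties", {
  contigs <- tibble::tibble(id = "rep", seq = strrep("ACGT", 300))
  ref_codes <- tibble::tibble(plasmid_id = c("rA", "rB"),
                              primary_id = c(1L, 2L))
  hits <- tibble::tibble(
    contig_id = "rep", subject_id = c("rA", "rB"),
    bit_score = c(500, 500), start = 0, end = 400
  )
  circ <- tibble::tibble(contig_id = "rep", circular = FALSE)
  cand <- tibble::tibble(contig_id = "rep", candidate = FALSE)
  out <- assign_contigs(contigs, hits, ref_codes, cand, circ)
  # tie broken to the smaller primary id; assigned once, never duplicated
  expect_equal(out$contig_map$unit_key, "cluster_1")
  expect_equal(sum(lengths(out$units$contig_ids)), 1)
})

test_that("unknown reference codes and short contigs are handled", {
  contigs <- tibble::tibble(id = c("c1", "tiny"),
                            seq = c(strrep("ACGT", 300), strrep("ACGT", 50)))
  ref_codes <- tibble::tibble(plasmid_id = "rA", primary_id = 1L)
  circ <- tibble::tibble(contig_id = contigs$id, circular = FALSE)
  cand <- tibble::tibble(contig_id = contigs$id, candidate = FALSE)
  bad <- tibble::tibble(contig_id = "c1", subject_id = "mystery",
                        bit_score = 100, start = 0, end = 100)
  expect_error(assign_contigs(contigs, bad, ref_codes, cand, circ),
               "unknown cluster")
  # a sub-length contig goes to the chromosome even with a hit
  hit <- tibble::tibble(contig_id = "tiny", subject_id = "rA",
                        bit_score = 100, start = 0, end = 100)
  out <- assign_contigs(contigs, hit, ref_codes, cand, circ,
                        min_contig_length = 500)
  expect_equal(out$contig_map$unit_key[out$contig_map$contig_id == "tiny"],
               "chromosome")
})

test_that("circular contigs are split out of multi-contig units", {
  units <- tibble::tibble(
    unit_key = c("cluster_1", "cluster_2", "cluster_3"),
    primary_id = 1:3,
    contig_ids = list(c("lin1", "circ1"), "circ2", c("a", "b", "cA", "cB"))
  )
  circ <- tibble::tibble(
    contig_id = c("lin1", "circ1", "circ2", "a", "b", "cA", "cB"),
    circular = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  )
  out <- split_circular_units(units, circ)
  has_set <- function(x) {
    any(vapply(out$contig_ids, function(s) identical(sort(s), sort(x)),
               logical(1)))
  }
  expect_true(has_set("lin1"))
  expect_true(has_set("circ1"))
  expect_true(has_set("circ2"))  # singleton unchanged
  expect_true(has_set(c("a", "b")))
  expect_true(has_set("cA") && has_set("cB"))
  expect_equal(sum(lengths(out$contig_ids)), 7)
})

test_that("repeat-only units are discarded unless circular or marker-bearing", {
  units <- tibble::tibble(
    unit_key = c("u1", "u2", "u3"),
    contig_ids = list(c("is1", "is2"), c("is3", "repl"), "circIS")
  )
  flags <- tibble::tibble(
    contig_id = c("is1", "is2", "is3", "repl", "circIS"),
    repeat_flagged = c(TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  circ <- tibble::tibble(contig_id = flags$contig_id,
                         circular = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  rep_hits <- tibble::tibble(contig_id = "repl")
  rel_hits <- tibble::tibble(contig_id = character(0))
  out <- discard_repeat_only_units(units, flags, rep_hits, rel_hits, circ)
  expect_setequal(out$units$unit_key, c("u2", "u3"))
  expect_setequal(out$discarded_contigs, c("is1", "is2"))
})

test_that("novelty uses a strict inequality at the loose threshold", {
  set.seed(42)
  refs <- tibble::tibble(plasmid_id = c("r1", "r2"),
                         seq = c(random_dna(8000), random_dna(8000)))
  db <- mob_cluster_build(refs)
  unit_seq <- mutate_seq(refs$seq[1], 0.03)
  contigs <- tibble::tibble(id = "u", seq = unit_seq)
  units <- tibble::tibble(unit_key = "k", contig_ids = list("u"))
  lab <- label_novelty(units, contigs, db)
  expect_equal(lab$closest_ref, "r1")
  expect_false(lab$novel)

  # exactly at the threshold: not novel (strictly greater than required)
  db_at <- db
  db_at$params$loose_threshold <- lab$closest_distance
  expect_false(label_novelty(units, contigs, db_at)$novel)
  db_below <- db
  db_below$params$loose_threshold <- lab$closest_distance - 1e-9
  expect_true(label_novelty(units, contigs, db_below)$novel)

  far <- tibble::tibble(id = "far", seq = random_dna(8000))
  units_far <- tibble::tibble(unit_key = "f", contig_ids = list("far"))
  expect_true(label_novelty(units_far, far, db)$novel)
})

test_that("reconstruction outputs partition the assembly", {
  st <- tiny_study(seed = 43)
  gg <- st$study$genomes[[1]]
  res <- mob_recon(gg$assembly, st$db, st$study$markers)
  outdir <- withr::local_tempdir()
  write_recon_outputs(res, gg$assembly, outdir)

  fas <- list.files(outdir, pattern = "\\.fasta$", full.names = TRUE)
  expect_length(fas, nrow(res$units) + 1) # units + chromosome
  ids <- unlist(lapply(fas, function(f) {
    if (file.size(f) == 0) character(0) else read_fasta(f)$id
  }))
  expect_setequal(ids, gg$assembly$id)
  expect_equal(anyDuplicated(ids), 0)

  report <- readr::read_tsv(file.path(outdir, "contig_report.tsv"),
                            show_col_types = FALSE)
  expect_equal(nrow(report), nrow(gg$assembly))
})

test_that("every circular contig survives to the final output", {
  st <- tiny_study(seed = 44)
  gg <- st$study$genomes[[1]]
  res <- mob_recon(gg$assembly, st$db, st$study$markers)
  circ_ids <- parse_circularity(gg$assembly)
  circ_ids <- circ_ids$contig_id[circ_ids$circular]
  in_units <- unlist(res$units$contig_ids)
  expect_true(all(circ_ids %in% in_units))
})
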