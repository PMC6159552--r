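test_that("truth tables bypass alignment in contig mapping", {
  truth <- tibble::tibble(contig_id = c("c1", "c2"),
                          origin_replicon_id = c("p1", "chromosome"))
  tm <- map_contigs_to_truth(NULL, truth = truth)
  expect_equal(tm$replicon_id, c("p1", "chromosome"))
})

test_that("alignment mapping keeps the best hit and applies the 50/50 rule", {
  set.seed(71)
  plasmid <- random_dna(8000)
  chrom <- random_dna(20000)
  genome <- tibble::tibble(id = c("p1", "chromosome"), seq = c(plasmid, chrom))

  asm <- tibble::tibble(
    id = c("cut", "lowcov", "chimera"),
    seq = c(substr(plasmid, 1000, 3999),                      # pure plasmid cut
            paste0(substr(plasmid, 4000, 4999), random_dna(2000)), # ~33% cov
            paste0(substr(plasmid, 5000, 6199),               # 60% plasmid
                   substr(chrom, 1, 800)))                    # 40% chromosome
  )
  tm <- map_contigs_to_truth(asm, genome)
  expect_equal(tm$replicon_id[tm$contig_id == "cut"], "p1")
  # under 50% coverage: discarded entirely
  expect_false("lowcov" %in% tm$contig_id)
  # chimeric contig maps to its single best-scoring origin
  expect_equal(tm$replicon_id[tm$contig_id == "chimera"], "p1")
})

test_that("base-level confusion counts follow the definitions", {
  assignments <- tibble::tibble(
    contig_id = c("a", "b", "c", "d"),
    length = c(95L, 5L, 88L, 12L),
    assigned_unit = c("1", "chromosome", "chromosome", "2")
  )
  truth <- tibble::tibble(
    contig_id = c("a", "b", "c", "d"),
    origin_replicon_id = c("p1", "p1", "chromosome", "chromosome")
  )
  conf <- base_confusion(assignments, map_contigs_to_truth(NULL, truth = truth))
  expect_equal(conf$tp, 95)
  expect_equal(conf$fn, 5)
  expect_equal(conf$tn, 88)
  expect_equal(conf$fp, 12)
  expect_equal(conf$sensitivity, 0.95)
  expect_equal(conf$specificity, 0.88)
  expect_equal(conf$tp + conf$fp + conf$tn + conf$fn, sum(assignments$length))
})

test_that("perfect and fully-missed assignments give the boundary rates", {
  truth <- tibble::tibble(contig_id = c("p", "c"),
                          origin_replicon_id = c("p1", "chromosome"))
  tm <- map_contigs_to_truth(NULL, truth = truth)
  perfect <- tibble::tibble(contig_id = c("p", "c"), length = c(100L, 900L),
                            assigned_unit = c("1", "chromosome"))
  conf <- base_confusion(perfect, tm)
  expect_equal(conf$sensitivity, 1)
  expect_equal(conf$specificity, 1)
  missed <- tibble::tibble(contig_id = c("p", "c"), length = c(100L, 900L),
                           assigned_unit = "chromosome")
  conf2 <- base_confusion(missed, tm)
  expect_equal(conf2$sensitivity, 0)
  expect_equal(conf2$specificity, 1)
  # unmapped contigs are excluded from the assessment
  extra <- dplyr::bind_rows(perfect,
                            tibble::tibble(contig_id = "junk", length = 50L,
                                           assigned_unit = "chromosome"))
  expect_equal(base_confusion(extra, tm), conf)
})

test_that("event taxonomy reproduces hand-enumerated scenarios", {
  truth <- tibble::tibble(
    contig_id = c("p1a", "p1b", "p2a", "p3a", "p3b", "p4a", "p5a",
                  "p6a", "p6b", "chr1"),
    origin_replicon_id = c("P1", "P1", "P2", "P3", "P3", "P4", "P5",
                           "P6", "P6", "chromosome")
  )
  tm <- map_contigs_to_truth(NULL, truth = truth)
  units <- tibble::tibble(
    unit_id = c("u1", "u2", "u3a", "u3b", "u6a", "u6b"),
    contig_ids = list(
      c("p1a", "p1b"),   # P1: correct
      c("p2a", "p4a"),   # P2 and P4: merged together
      "p3a", "p3b",      # P3: split over two pure units
      c("p6a", "chr1"), "p6b" # P6: split AND merged with chromosome -> hybrid
    )
  )
  ev <- classify_events(units, tm)
  got <- setNames(ev$event, ev$plasmid_id)
  expect_equal(unname(got["P1"]), "correct")
  expect_equal(unname(got["P2"]), "merge")
  expect_equal(unname(got["P4"]), "merge")
  expect_equal(unname(got["P3"]), "split")
  expect_equal(unname(got["P6"]), "hybrid")
  expect_equal(unname(got["P5"]), "missed")

  tab <- summarize_events(ev)
  count_of <- function(m) tab$count[tab$metric == m]
  expect_equal(count_of("Total plasmids"), 6)
  expect_equal(count_of("Plasmids identified"), 5)
  expect_equal(count_of("Correctly partitioned plasmids"), 1)
  expect_equal(count_of("Plasmids merged into single clusters"), 2)
  expect_equal(count_of("Plasmids split across multiple clusters"), 1)
  expect_equal(count_of("Plasmids with a combination of splits and merges"), 1)
  expect_equal(count_of("Plasmids missed"), 1)
  # classes partition the plasmids
  expect_equal(sum(tab$count[tab$metric != "Total plasmids" &
                               tab$metric != "Plasmids identified"]),
               count_of("Total plasmids"))
})

test_that("overlapping units are rejected", {
  truth <- tibble::tibble(contig_id = "x", origin_replicon_id = "P1")
  units <- tibble::tibble(unit_id = c("u1", "u2"),
                          contig_ids = list("x", "x"))
  expect_error(classify_events(units, map_contigs_to_truth(NULL, truth = truth)),
               "overlapping")
})

test_that("end-to-end reconstruction on unambiguous fixtures is perfect", {
  st <- tiny_study(seed = 72)
  gg <- st$study$genomes[[1]]
  res <- mob_recon(gg$assembly, st$db, st$study$markers)
  # assess against the closed genome with the 50/50 best-hit mapping rule;
  # the shared repeat contig maps to its single best origin
  tm <- map_contigs_to_truth(
    gg$assembly,
    dplyr::select(gg$genome$replicons, id = "replicon_id", "seq"))
  conf <- base_confusion(tidy(res), tm)
  ev <- classify_events(res$units, tm)
  expect_gte(conf$sensitivity, 0.99)
  expect_gte(conf$specificity, 0.99)
  expect_true(all(ev$event == "correct"))
})

test_that("a repeat shared with the references joins exactly one unit", {
  # when the repeat element is part of two reference plasmids from different
  # clusters, a repeat contig hits both; winner-take-all must place it once
  set.seed(73)
  rep_el <- random_dna(1000)
  anc1 <- paste0(random_dna(4000), rep_el, random_dna(4000))
  anc2 <- paste0(random_dna(5000), rep_el, random_dna(5000))
  db <- mob_cluster_build(tibble::tibble(
    plasmid_id = c("r1", "r2"), seq = c(anc1, anc2)
  ))
  markers <- list(
    replicon = tibble::tibble(id = "IncA_1", seq = random_dna(700)),
    relaxase = tibble::tibble(id = "MOBF_1", seq = random_dna(900))
  )
  asm <- tibble::tibble(
    id = c("body1", "body2", "is1"),
    seq = c(substr(anc1, 1, 4000), substr(anc2, 1, 5000), rep_el)
  )
  res <- mob_recon(asm, db, markers)
  placements <- sum(vapply(res$units$contig_ids, function(x) "is1" %in% x,
                           logical(1)))
  expect_equal(placements, 1)
})
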