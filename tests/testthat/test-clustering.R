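test_that("pairwise distance matrix has the required shape", {
  set.seed(21)
  one <- tibble::tibble(plasmid_id = "p1", seq = random_dna(2000))
  m1 <- mob_pairwise_distances(one)
  expect_equal(m1, matrix(0, 1, 1, dimnames = list("p1", "p1")))

  x <- random_dna(3000)
  two <- tibble::tibble(plasmid_id = c("a", "b"), seq = c(x, x))
  m2 <- mob_pairwise_distances(two)
  expect_equal(m2["a", "b"], 0)
  expect_equal(m2, t(m2))
})

test_that("distance ordering reflects simulated divergence", {
  set.seed(22)
  anc <- random_dna(10000)
  tbl <- tibble::tibble(
    plasmid_id = c("same", "near", "far"),
    seq = c(anc, mutate_seq(anc, 0.05), mutate_seq(anc, 0.2))
  )
  m <- mob_pairwise_distances(tbl)
  expect_lt(m["same", "near"], m["same", "far"])
})

test_that("unsketchable records are reported by name", {
  bad <- tibble::tibble(plasmid_id = c("ok", "tiny"),
                        seq = c(strrep("ACGT", 300), "ACGT"))
  expect_error(mob_pairwise_distances(bad), "tiny")
})

test_that("single-linkage partition equals threshold-graph components", {
  # trivial thresholds
  set.seed(23)
  m <- random_dist_matrix(8)
  expect_equal(max(mob_single_linkage(m, 0)), 8L)
  expect_equal(max(mob_single_linkage(m, 1)), 1L)

  # chaining: A-B and B-C linked, A-C far
  chain <- matrix(c(0, 0.04, 0.30,
                    0.04, 0, 0.04,
                    0.30, 0.04, 0), 3, 3,
                  dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(unname(mob_single_linkage(chain, 0.05)), c(1L, 1L, 1L))

  # randomized agreement with the union-find oracle
  set.seed(24)
  for (i in 1:25) {
    m <- random_dist_matrix(20)
    t <- runif(1)
    got <- mob_single_linkage(m, t)
    want <- uf_components(m, t)
    expect_equal(unname(got), unname(want))
  }
})

test_that("cluster codes separate at the two thresholds as expected", {
  set.seed(25)
  anc <- random_dna(20000)
  tbl <- tibble::tibble(
    plasmid_id = c("a", "b", "c", "d"),
    seq = c(anc,
            mutate_seq(anc, 2e-4),  # within strict of a
            mutate_seq(anc, 0.012), # within loose only
            random_dna(20000))      # unrelated
  )
  db <- mob_cluster_build(tbl)
  rec <- tidy(db)
  code <- function(id) rec[rec$plasmid_id == id, ]
  expect_equal(code("b")$primary_id, code("a")$primary_id)
  expect_equal(code("b")$secondary_id, code("a")$secondary_id)
  expect_equal(code("c")$primary_id, code("a")$primary_id)
  expect_false(code("c")$secondary_id == code("a")$secondary_id)
  expect_false(code("d")$primary_id == code("a")$primary_id)
  # nesting: same secondary implies same primary
  nest <- tapply(rec$primary_id, rec$secondary_id, dplyr::n_distinct)
  expect_true(all(nest == 1))
})

test_that("threshold order is validated", {
  tbl <- tibble::tibble(plasmid_id = "p", seq = strrep("ACGT", 500))
  expect_error(mob_cluster_build(tbl, loose_threshold = 0.001,
                                 strict_threshold = 0.05),
               "strict_threshold")
})

test_that("incremental updates inherit or mint codes and never touch old ones", {
  set.seed(26)
  anc1 <- random_dna(15000)
  anc2 <- random_dna(15000)
  base <- tibble::tibble(
    plasmid_id = c("p1", "p2", "q1"),
    seq = c(anc1, mutate_seq(anc1, 0.01), anc2)
  )
  db <- mob_cluster_build(base)
  before <- tidy(db)

  new <- tibble::tibble(
    plasmid_id = c("copy", "cousin", "stranger"),
    seq = c(anc1,                  # exact copy of p1
            mutate_seq(anc2, 0.02), # loose neighbour of q1
            random_dna(15000))      # unrelated
  )
  db2 <- mob_cluster_update(db, new)
  after <- tidy(db2)

  # pre-existing codes are bitwise identical
  expect_identical(before, after[match(before$plasmid_id, after$plasmid_id), ])

  p1 <- after[after$plasmid_id == "p1", ]
  expect_equal(after[after$plasmid_id == "copy", ]$cluster_code, p1$cluster_code)

  q1 <- after[after$plasmid_id == "q1", ]
  cousin <- after[after$plasmid_id == "cousin", ]
  expect_equal(cousin$primary_id, q1$primary_id)
  expect_gt(cousin$secondary_id, max(before$secondary_id))

  stranger <- after[after$plasmid_id == "stranger", ]
  expect_gt(stranger$primary_id, max(before$primary_id))
  expect_gt(stranger$secondary_id, max(before$secondary_id))
})

test_that("duplicate ids and bridge records are handled", {
  set.seed(27)
  anc1 <- random_dna(12000)
  anc2 <- random_dna(12000)
  db <- mob_cluster_build(tibble::tibble(
    plasmid_id = c("a", "b"), seq = c(anc1, anc2)
  ))
  expect_error(mob_cluster_update(db, tibble::tibble(
    plasmid_id = "a", seq = anc1
  )), "duplicate")

  # a half-and-half mosaic links both clusters at <= 0.05
  mosaic <- paste0(substr(anc1, 1, 6000), substr(anc2, 1, 6000))
  expect_warning(
    db2 <- mob_cluster_update(db, tibble::tibble(plasmid_id = "m",
                                                 seq = mosaic)),
    "bridge")
  after <- tidy(db2)
  # the two original clusters were not merged
  expect_false(after$primary_id[after$plasmid_id == "a"] ==
                 after$primary_id[after$plasmid_id == "b"])
  expect_true(after$primary_id[after$plasmid_id == "m"] %in%
                after$primary_id[after$plasmid_id %in% c("a", "b")])
})

test_that("databases round-trip through a directory", {
  set.seed(28)
  db <- mob_cluster_build(tibble::tibble(
    plasmid_id = c("x", "y"),
    seq = replicate(2, random_dna(5000))
  ))
  dir <- withr::local_tempdir()
  write_mob_db(db, dir)
  expect_true(file.exists(file.path(dir, "refs.fasta")))
  back <- read_mob_db(dir)
  expect_equal(tidy(back), tidy(db))
  expect_identical(back$sketches$x$hashes, db$sketches$x$hashes)
  expect_equal(back$counters, db$counters)
  # header carries the cluster code
  fa <- readLines(file.path(dir, "refs.fasta"))
  expect_true(any(grepl("^>x\\|cluster=[0-9]+\\.[0-9]+$", fa)))
})
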