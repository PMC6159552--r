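#' Random DNA sequence
#'
#' @param n Length in bases.
#' @return A single DNA string over A/C/G/T.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Mutate a DNA sequence by random substitutions
#'
#' Substitution-only mutation (no indels), so coordinates of planted features
#' remain valid. Each base is substituted independently with probability
#' `rate`, always to a different base.
#'
#' @param seq A DNA string.
#' @param rate Per-base substitution probability in \[0, 1\].
#' @return The mutated string.
#' @export
mutate_seq <- function(seq, rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  idx <- which(stats::runif(length(ch)) < rate)
  if (length(idx)) {
    ch[idx] <- vapply(ch[idx], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1), USE.NAMES = FALSE)
  }
  paste(ch, collapse = "")
}

insert_at <- function(seq, pos, ins) {
  # pos is 0-based: the insert begins at coordinate pos of the result
  paste0(substr(seq, 1, pos), ins, substr(seq, pos + 1, nchar(seq)))
}

#' Simulation configuration
#'
#' Central parameter record for the synthetic-data generator. Defaults
#' describe the standard study conditions used throughout the test-suite:
#' three reference clusters of closely related plasmids (per-lineage
#' substitution rate 0.01, independent cluster ancestors), 8-20 kb plasmids,
#' a 120 kb chromosome, genome plasmids copied from reference members at
#' rate 0.02, and a 1 kb repeat element shared between the chromosome and
#' one plasmid.
#'
#' @param seed Mandatory integer RNG seed.
#' @param n_clusters Number of reference clusters.
#' @param cluster_sizes Integer vector of members per cluster (recycled to
#'   `n_clusters`).
#' @param within_rate Per-lineage substitution rate inside a cluster.
#' @param plasmid_length_range Ancestor plasmid length range (bases).
#' @param chromosome_length Chromosome length (bases).
#' @param plasmid_rate Substitution rate of a genome plasmid relative to its
#'   source reference member.
#' @param n_plasmids_per_genome Plasmids per simulated genome.
#' @param repeat_length Length of the shared repeat element (bases).
#' @param share_repeat Insert one repeat copy into the chromosome and one
#'   into the first plasmid of each genome.
#' @param cut_at_repeats Place assembly breakpoints at repeat boundaries so
#'   repeats become standalone contigs.
#' @param n_random_cuts Extra random breakpoints per plasmid.
#' @param n_chromosome_cuts Random breakpoints on the chromosome.
#' @param keep_whole_smallest Leave the smallest plasmid of each genome
#'   uncut and tagged `circular=true`.
#' @param min_fragment Minimum fragment length between breakpoints (bases).
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(seed, n_clusters = 3L, cluster_sizes = c(4L, 3L, 3L),
                       within_rate = 0.01,
                       plasmid_length_range = c(8000L, 20000L),
                       chromosome_length = 120000L, plasmid_rate = 0.02,
                       n_plasmids_per_genome = 3L, repeat_length = 1000L,
                       share_repeat = TRUE, cut_at_repeats = TRUE,
                       n_random_cuts = 2L, n_chromosome_cuts = 4L,
                       keep_whole_smallest = TRUE, min_fragment = 600L) {
  if (missing(seed) || is.null(seed)) abort("seed is mandatory")
  cfg <- list(
    seed = as.integer(seed), n_clusters = as.integer(n_clusters),
    cluster_sizes = rep_len(as.integer(cluster_sizes), n_clusters),
    within_rate = within_rate,
    plasmid_length_range = as.integer(plasmid_length_range),
    chromosome_length = as.integer(chromosome_length),
    plasmid_rate = plasmid_rate,
    n_plasmids_per_genome = as.integer(n_plasmids_per_genome),
    repeat_length = as.integer(repeat_length),
    share_repeat = isTRUE(share_repeat),
    cut_at_repeats = isTRUE(cut_at_repeats),
    n_random_cuts = as.integer(n_random_cuts),
    n_chromosome_cuts = as.integer(n_chromosome_cuts),
    keep_whole_smallest = isTRUE(keep_whole_smallest),
    min_fragment = as.integer(min_fragment)
  )
  rates <- c(cfg$within_rate, cfg$plasmid_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must be in [0, 1]")
  if (any(cfg$plasmid_length_range <= 0) || cfg$chromosome_length <= 0) {
    abort("lengths must be positive")
  }
  # independent ancestors sit near distance saturation; within-cluster
  # pairwise divergence (~2 * within_rate) must stay well clear of it
  if (2 * cfg$within_rate >= 0.3) {
    abort("within-cluster rate makes clusters indistinguishable")
  }
  structure(cfg, class = "sim_config")
}

#' Generate synthetic marker databases
#'
#' Builds random (seeded) replicon, relaxase, MPF, oriT and repeat-element
#' databases with one variant per family. Marker ids follow the
#' `<family>_<n>` naming convention that the typing code parses. The
#' sequences are random DNA — the databases exercise the algorithms, not
#' real marker biology.
#'
#' @param config A [sim_config()].
#' @return Named list of sequence tibbles: `replicon`, `relaxase`, `mpf`,
#'   `orit`, `repeat`.
#' @export
simulate_marker_dbs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  n <- max(config$n_clusters, 4L)
  fam <- function(prefixes, len_lo, len_hi) {
    tibble(
      id = paste0(prefixes, "_1"),
      seq = map_chr(prefixes, ~ random_dna(sample(len_lo:len_hi, 1)))
    )
  }
  rep_fams <- paste0("Inc", LETTERS[seq_len(n)])
  rel_fams <- paste0("MOB", c("F", "H", "Q", "P", "V", "C")[seq_len(min(n, 6))])
  if (n > 6) rel_fams <- c(rel_fams, paste0("MOBX", seq_len(n - 6)))
  list(
    replicon = fam(rep_fams, 800L, 1500L),
    relaxase = fam(rel_fams, 900L, 1500L),
    mpf = fam(paste0("MPF", c("T", "F", "I", "G")), 800L, 1200L),
    orit = fam(paste0("oriT", seq_len(4L)), 300L, 500L),
    "repeat" = tibble(id = "ISmk1_1", seq = random_dna(config$repeat_length))
  )
}

#' Simulate a clustered reference plasmid set
#'
#' Draws one independent random ancestor per cluster, plants a
#' cluster-specific replicon and relaxase marker into it, and derives each
#' member by substitution at `within_rate` per lineage, so expected pairwise
#' within-cluster divergence is about twice the rate while between-cluster
#' distances saturate. The planted partition is returned for
#' parameter-recovery tests.
#'
#' @param config A [sim_config()].
#' @param markers Marker databases from [simulate_marker_dbs()] (generated
#'   from `config` when omitted).
#' @return A list: `plasmids` (tibble `plasmid_id`, `seq`, `true_cluster`),
#'   `truth_partition` (named integer vector), `marker_map` (tibble of
#'   planted marker coordinates) and `markers`.
#' @export
simulate_references <- function(config, markers = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(markers)) markers <- simulate_marker_dbs(config)
  set.seed(config$seed + 202L)
  plasmids <- list(); marker_rows <- list()
  for (cl in seq_len(config$n_clusters)) {
    len <- sample(config$plasmid_length_range[1]:config$plasmid_length_range[2], 1)
    anc <- random_dna(len)
    plants <- tibble(
      marker_id = c(markers$replicon$id[cl], markers$relaxase$id[cl]),
      category = c("replicon", "relaxase"),
      seq = c(markers$replicon$seq[cl], markers$relaxase$seq[cl])
    )
    # place markers in non-overlapping windows of the ancestor
    pos <- 0L
    plants$start <- NA_integer_; plants$end <- NA_integer_
    gap <- floor(len / (nrow(plants) + 1))
    for (j in seq_len(nrow(plants))) {
      mlen <- nchar(plants$seq[j])
      if (gap * j + mlen > len) abort("plasmid too short for planted markers")
      plants$start[j] <- gap * (j - 1) + 100L
      plants$end[j] <- plants$start[j] + mlen
      anc <- paste0(substr(anc, 1, plants$start[j]), plants$seq[j],
                    substr(anc, plants$end[j] + 1, len))
    }
    for (m in seq_len(config$cluster_sizes[cl])) {
      id <- paste0("ref_c", cl, "_m", m)
      plasmids[[id]] <- tibble(
        plasmid_id = id,
        seq = mutate_seq(anc, config$within_rate),
        true_cluster = cl
      )
      marker_rows[[id]] <- mutate(select(plants, -"seq"), plasmid_id = id)
    }
  }
  plasmids <- bind_rows(plasmids)
  list(
    plasmids = plasmids,
    truth_partition = setNames(plasmids$true_cluster, plasmids$plasmid_id),
    marker_map = bind_rows(marker_rows),
    markers = markers
  )
}

#' Simulate one closed genome (chromosome plus plasmids)
#'
#' Plasmids are substitution-mutated copies (at `plasmid_rate`) of one
#' reference member from each of `n_plasmids_per_genome` distinct clusters.
#' Optionally one copy of the shared repeat element is inserted into the
#' chromosome and one into the first plasmid; all placements are recorded.
#' The repeat is a genome-specific insertion and is absent from the
#' reference plasmids.
#'
#' @param config A [sim_config()].
#' @param references Output of [simulate_references()].
#' @param genome_seed RNG seed of this genome (default `config$seed + 303`).
#' @return A list: `replicons` (tibble `replicon_id`, `seq`, `type`,
#'   `source_ref`, `source_cluster`), `repeat_placements`,
#'   `marker_placements` and `repeat_seq`.
#' @export
simulate_genome <- function(config, references,
                            genome_seed = config$seed + 303L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(genome_seed)
  n_p <- config$n_plasmids_per_genome
  if (n_p > config$n_clusters) {
    abort("n_plasmids_per_genome exceeds the number of reference clusters")
  }
  clusters <- sort(sample(seq_len(config$n_clusters), n_p))
  refs <- references$plasmids
  members <- map_chr(clusters, function(cl) {
    ids <- refs$plasmid_id[refs$true_cluster == cl]
    sample(ids, 1)
  })

  rep_seq <- references$markers[["repeat"]]$seq[1]
  rep_len <- nchar(rep_seq)
  repeat_rows <- list(); marker_rows <- list(); rows <- list()

  for (i in seq_along(members)) {
    src <- members[i]
    pid <- paste0("p", i)
    sq <- mutate_seq(refs$seq[refs$plasmid_id == src], config$plasmid_rate)
    mk <- references$marker_map |>
      filter(.data$plasmid_id == src) |>
      mutate(replicon_id = pid)
    if (config$share_repeat && i == 1L) {
      # insert outside planted marker intervals
      pos <- pick_insert_pos(nchar(sq), mk$start, mk$end, margin = 200L)
      sq <- insert_at(sq, pos, rep_seq)
      shift <- mk$start >= pos
      mk$start[shift] <- mk$start[shift] + rep_len
      mk$end[shift] <- mk$end[shift] + rep_len
      repeat_rows[[pid]] <- tibble(replicon_id = pid, start = pos,
                                   end = pos + rep_len)
    }
    marker_rows[[pid]] <- mk
    rows[[pid]] <- tibble(replicon_id = pid, seq = sq, type = "plasmid",
                          source_ref = src, source_cluster = clusters[i])
  }

  chrom <- random_dna(config$chromosome_length)
  if (config$share_repeat) {
    pos <- sample(seq(1000L, config$chromosome_length - 1000L), 1)
    chrom <- insert_at(chrom, pos, rep_seq)
    repeat_rows[["chromosome"]] <- tibble(replicon_id = "chromosome",
                                          start = pos, end = pos + rep_len)
  }
  rows[["chromosome"]] <- tibble(replicon_id = "chromosome", seq = chrom,
                                 type = "chromosome",
                                 source_ref = NA_character_,
                                 source_cluster = NA_integer_)
  list(
    replicons = bind_rows(rows),
    repeat_placements = if (length(repeat_rows)) bind_rows(repeat_rows) else
      tibble(replicon_id = character(), start = integer(), end = integer()),
    marker_placements = bind_rows(marker_rows),
    repeat_seq = rep_seq
  )
}

pick_insert_pos <- function(len, starts, ends, margin = 200L, tries = 1000L) {
  for (t in seq_len(tries)) {
    pos <- sample(seq(margin, len - margin), 1)
    if (length(starts) == 0 ||
        all(pos <= starts - margin | pos >= ends + margin)) {
      return(pos)
    }
  }
  abort("could not place insertion without overlapping forced placements")
}

#' Fragment a closed genome into a draft assembly with ground truth
#'
#' Each replicon is treated as circular and cut into contigs at breakpoints:
#' repeat boundaries (when `cut_at_repeats`, so repeat copies become
#' standalone contigs) plus random extra cuts that avoid planted markers.
#' For a circular molecule, n cuts yield n fragments; the fragment spanning
#' the sequence origin has `origin_end < origin_start` in the truth table.
#' Replicons with no cuts are emitted whole with a `circular=true` header
#' token; by default the smallest plasmid is left whole.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @param assembly_seed RNG seed for breakpoint placement (default
#'   `config$seed + 404`).
#' @param contig_prefix Prefix of generated contig ids.
#' @return A list: `assembly` (sequence tibble with `header` carrying
#'   circularity tokens) and `truth` (tibble `contig_id`,
#'   `origin_replicon_id`, `origin_start`, `origin_end`, `circular`,
#'   `is_repeat`, `planted_markers`).
#' @export
fragment_assembly <- function(config, genome,
                              assembly_seed = config$seed + 404L,
                              contig_prefix = "ctg") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(assembly_seed)
  reps <- genome$replicons
  plasmid_lengths <- nchar(reps$seq[reps$type == "plasmid"])
  whole_id <- if (config$keep_whole_smallest && any(reps$type == "plasmid")) {
    reps$replicon_id[reps$type == "plasmid"][which.min(plasmid_lengths)]
  } else ""

  out_seq <- list(); out_truth <- list(); k <- 0L
  for (i in seq_len(nrow(reps))) {
    rid <- reps$replicon_id[i]
    sq <- reps$seq[i]
    len <- nchar(sq)
    repeats <- genome$repeat_placements |>
      filter(.data$replicon_id == rid)
    markers <- genome$marker_placements |>
      filter(.data$replicon_id == rid)

    cuts <- integer(0)
    if (rid != whole_id) {
      if (config$cut_at_repeats && nrow(repeats)) {
        cuts <- c(cuts, repeats$start, repeats$end)
      }
      n_rand <- if (reps$type[i] == "chromosome") config$n_chromosome_cuts
                else config$n_random_cuts
      if (n_rand * config$min_fragment > len) {
        abort(paste0("contig length configuration exceeds replicon length for ",
                     rid))
      }
      forbidden_s <- c(markers$start, repeats$start)
      forbidden_e <- c(markers$end, repeats$end)
      for (j in seq_len(n_rand)) {
        cuts <- c(cuts, pick_cut(len, cuts, forbidden_s, forbidden_e,
                                 config$min_fragment))
      }
      cuts <- sort(unique(cuts))
    }

    if (length(cuts) == 0) {
      k <- k + 1L
      cid <- sprintf("%s_%04d", contig_prefix, k)
      out_seq[[cid]] <- tibble(id = cid, seq = sq,
                               header = paste0(cid, " circular=true"))
      out_truth[[cid]] <- truth_row(cid, rid, 0L, len, TRUE, repeats, markers)
      next
    }
    n <- length(cuts)
    for (j in seq_len(n)) {
      a <- cuts[j]
      b <- if (j < n) cuts[j + 1] else cuts[1]
      frag <- if (j < n) substr(sq, a + 1, b)
              else paste0(substr(sq, a + 1, len), substr(sq, 1, b))
      if (nchar(frag) == 0) next
      k <- k + 1L
      cid <- sprintf("%s_%04d", contig_prefix, k)
      out_seq[[cid]] <- tibble(id = cid, seq = frag, header = cid)
      out_truth[[cid]] <- truth_row(cid, rid, a, b, FALSE, repeats, markers)
    }
  }
  list(assembly = bind_rows(out_seq), truth = bind_rows(out_truth))
}

pick_cut <- function(len, cuts, forb_s, forb_e, min_fragment, tries = 2000L) {
  for (t in seq_len(tries)) {
    pos <- sample.int(len, 1)
    ok_forb <- length(forb_s) == 0 || all(pos <= forb_s | pos >= forb_e)
    ok_gap <- length(cuts) == 0 || all(abs(pos - cuts) >= min_fragment)
    if (ok_forb && ok_gap) return(pos)
  }
  abort("could not place a breakpoint honouring the fragment constraints")
}

truth_row <- function(cid, rid, a, b, circular, repeats, markers) {
  # interval [a, b) on the origin replicon; b <= a encodes origin wrap
  covers <- function(s, e) {
    if (b > a) s >= a & e <= b else (s >= a) | (e <= b)
  }
  inside <- if (nrow(markers)) covers(markers$start, markers$end) else logical(0)
  is_rep <- nrow(repeats) > 0 && any(repeats$start == a & repeats$end == b)
  tibble(
    contig_id = cid, origin_replicon_id = rid,
    origin_start = as.integer(a), origin_end = as.integer(b),
    circular = circular,
    is_repeat = is_rep,
    planted_markers = if (any(inside)) {
      paste(markers$marker_id[inside], collapse = ",")
    } else ""
  )
}

#' Simulate a complete study: references, genomes and draft assemblies
#'
#' Convenience orchestrator used by the test-suite and the acceptance
#' script: generates marker databases and the clustered reference set once,
#' then `n_genomes` genomes (each with fresh RNG substream) and their
#' fragmented assemblies with truth tables.
#'
#' @param config A [sim_config()].
#' @param n_genomes Number of genomes to simulate.
#' @return A list: `markers`, `references`, and `genomes` — a list of
#'   per-genome lists with `genome`, `assembly` and `truth`.
#' @export
simulate_study <- function(config, n_genomes = 10L) {
  stopifnot(inherits(config, "sim_config"))
  refs <- simulate_references(config)
  genomes <- map(seq_len(n_genomes), function(g) {
    gen <- simulate_genome(config, refs, genome_seed = config$seed + 1000L + g)
    frag <- fragment_assembly(config, gen,
                              assembly_seed = config$seed + 2000L + g,
                              contig_prefix = paste0("g", g, "_ctg"))
    list(genome = gen, assembly = frag$assembly, truth = frag$truth)
  })
  list(markers = refs$markers, references = refs, genomes = genomes)
}
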