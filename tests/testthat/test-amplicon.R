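# Demultiplexing, cleaning, clustering, k-mer search and taxonomy.

mk_read <- function(id, sequence, q = "I") {
  tibble::tibble(id = id, sequence = sequence,
                 quality = strrep(q, nchar(sequence)))
}

test_that("demultiplexing recognizes barcode + tag + primer structure", {
  tags <- tag_pair()
  barcodes <- tibble::tibble(sample_id = c("s1", "s2"),
                             barcode = c("AAAAACCCCC", "GGGGGTTTTT"))
  strep_fwd <- "CTAACCAGAAAGGGACGGCT"   # degenerate W instantiated as A
  insert <- strrep("ACGT", 60)
  reads <- dplyr::bind_rows(
    mk_read("r1", paste0("AAAAACCCCC", tags$forward_tag, strep_fwd, insert)),
    mk_read("r2", paste0("GGGGGTTTTT", tags$forward_tag, strep_fwd, insert)),
    mk_read("r3", paste0("TTTTTTTTTT", tags$forward_tag, strep_fwd, insert)),
    mk_read("r4", paste0("AAAAACCCCC", strrep("A", 22), strep_fwd, insert)),
    mk_read("r5", paste0("AAAAACCCCC", tags$forward_tag, strrep("T", 20), insert)))
  out <- demultiplex(reads, barcodes, the_panel)
  expect_equal(nrow(out$records) + nrow(out$rejects), nrow(reads))
  expect_equal(out$records$read_id, c("r1", "r2"))
  expect_equal(out$records$sample_id, c("s1", "s2"))
  expect_equal(out$records$primer_set, c("streptococcus", "streptococcus"))
  expect_equal(out$records$insert, c(insert, insert))
  expect_equal(nchar(out$records$insert_quality), rep(nchar(insert), 2))
  expect_equal(sort(out$rejects$reason), c("barcode", "primer", "tag"))
})

test_that("one barcode error is tolerated only with max_mismatch = 1", {
  tags <- tag_pair()
  barcodes <- tibble::tibble(sample_id = c("s1", "s2"),
                             barcode = c("AAAAACCCCC", "GGGGGTTTTT"))
  read <- mk_read("r1", paste0("AAAAACCCCA", tags$forward_tag,
                               "CTAACCAGAAAGGGACGGCT", strrep("ACGT", 60)))
  strict <- demultiplex(read, barcodes, the_panel, max_mismatch = 0L)
  expect_equal(nrow(strict$records), 0L)
  expect_equal(strict$rejects$reason, "barcode")
  loose <- demultiplex(read, barcodes, the_panel, max_mismatch = 1L)
  expect_equal(loose$records$sample_id, "s1")
  # colliding barcodes are a configuration error at the same tolerance
  close_bc <- tibble::tibble(sample_id = c("s1", "s2"),
                             barcode = c("AAAAACCCCC", "AAAAACCCCA"))
  expect_error(demultiplex(read, close_bc, the_panel, max_mismatch = 1L),
               "configuration error")
})

test_that("untagged species assays never receive reads", {
  tags <- tag_pair()
  barcodes <- tibble::tibble(sample_id = "s1", barcode = "AAAAACCCCC")
  ecoli_fwd <- "GTTAATACCTTTGCTCATTGA"
  read <- mk_read("r1", paste0("AAAAACCCCC", tags$forward_tag, ecoli_fwd,
                               strrep("ACGT", 60)))
  out <- demultiplex(read, barcodes, the_panel)
  expect_equal(nrow(out$records), 0L)
  expect_equal(out$rejects$reason, "primer")
})

test_that("cleaning applies the accuracy and length gates", {
  rec <- function(id, len, q) {
    tibble::tibble(read_id = id, sample_id = "s", primer_set = "bacteria_B",
                   insert = strrep("A", len), insert_quality = strrep(q, len))
  }
  q20 <- rawToChar(as.raw(33 + 20))  # accuracy 0.99
  q10 <- rawToChar(as.raw(33 + 10))  # accuracy 0.90
  q15 <- rawToChar(as.raw(33 + 15))  # accuracy ~0.968
  recs <- dplyr::bind_rows(rec("a", 250, q20), rec("b", 250, q10),
                           rec("c", 199, q15), rec("d", 200, q15))
  out <- quality_filter(recs)
  expect_setequal(out$read_id, c("a", "d"))
})

test_that("greedy clustering respects the identity threshold", {
  withr::local_seed(43)
  base <- rand_seq(300)
  recs <- tibble::tibble(insert = rep(base, 5),
                         insert_quality = strrep("I", 300))
  one <- greedy_cluster(recs)
  expect_equal(nrow(one), 1L)
  expect_equal(one$member_count, 5L)

  flip <- function(s, pos) {
    for (p in pos) {
      old <- substr(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    s
  }
  # 1 mismatch in 300 bp = 99.67% identity: joins
  two_similar <- tibble::tibble(insert = c(base, flip(base, 7)),
                                insert_quality = strrep("I", 300))
  expect_equal(nrow(greedy_cluster(two_similar)), 1L)
  # 2 mismatches = 99.33%: splits
  two_far <- tibble::tibble(insert = c(base, flip(base, c(7, 100))),
                            insert_quality = strrep("I", 300))
  expect_equal(nrow(greedy_cluster(two_far)), 2L)
})

test_that("clustering is invariant to input order and conserves reads", {
  withr::with_seed(19, {
    pool <- c(replicate(3, rand_seq(280)))
    seqs <- sample(pool, 40, replace = TRUE)
    recs <- tibble::tibble(insert = seqs, insert_quality = strrep("I", 280))
    a <- greedy_cluster(recs)
    b <- greedy_cluster(recs[sample(nrow(recs)), ])
    expect_equal(a$centroid, b$centroid)
    expect_equal(a$member_count, b$member_count)
    expect_equal(sum(a$member_count), 40L)
  })
})

test_that("k-mer similarity matches the brute-force set oracle", {
  q <- strrep("I", 60)
  s <- rand_seq(60)
  expect_equal(kmer_similarity(s, s, quality = q, min_kmers = 5), 100)
  expect_equal(kmer_similarity(strrep("A", 60), strrep("C", 60),
                               quality = q, min_kmers = 1), 0)
  withr::with_seed(23, {
    for (rep in 1:200) {
      a <- rand_seq(sample(20:60, 1))
      b <- rand_seq(sample(20:60, 1))
      got <- kmer_similarity(a, b, quality = strrep("I", nchar(a)),
                             min_kmers = 1)
      expect_equal(got, oracle_kmer_similarity(a, b), tolerance = 1e-12)
    }
  })
})

test_that("low-quality windows and short queries are excluded", {
  withr::local_seed(41)
  s <- rand_seq(40)
  # one low-quality base knocks out the k windows covering it
  q <- strrep("I", 40)
  substr(q, 20, 20) <- "!"   # Phred 0
  km_all <- kmer_similarity(s, s, quality = strrep("I", 40), min_kmers = 1)
  expect_equal(km_all, 100)
  km_gap <- kmer_similarity(s, s, quality = q, min_kmers = 1)
  expect_equal(km_gap, 100)  # remaining kmers still all match
  # too few usable kmers -> skip sentinel
  expect_true(is.na(kmer_similarity(s, s, quality = q, min_kmers = 30)))
})

test_that("search returns the relative best band above the cutoff", {
  withr::local_seed(37)
  # engineered database: similarities ~98, ~97.5 and ~90
  q <- rand_seq(200)
  mk_ref <- function(target_sim) {
    kms <- nchar(q) - 7
    keep <- round(target_sim / 100 * kms)
    paste0(substr(q, 1, keep + 7), strrep("A", 250))
  }
  db <- tibble::tibble(
    reference_id = c("hi", "mid", "lo"),
    sequence = c(mk_ref(98), mk_ref(97.5), mk_ref(90)))
  hits <- kmer_search(q, db, quality = strrep("I", nchar(q)))
  sims <- setNames(hits$similarity, hits$reference_id)
  expect_true(all(c("hi", "mid") %in% hits$reference_id))
  expect_false("lo" %in% hits$reference_id)
  expect_true(all(diff(hits$similarity) <= 0))
  # cutoff empties the hit list when nothing reaches 50%
  none <- kmer_search(rand_seq(200), tibble::tibble(
    reference_id = "x", sequence = strrep("A", 300)),
    quality = strrep("I", 200))
  expect_equal(nrow(none), 0L)
  expect_error(kmer_search(q, tibble::tibble(reference_id = character(0),
                                             sequence = character(0))),
               "empty")
  # top hit equals the exhaustive argmax
  withr::with_seed(29, {
    db2 <- tibble::tibble(reference_id = sprintf("ref%02d", 1:40),
                          sequence = replicate(40, rand_seq(150)))
    db2$sequence[17] <- paste0(substr(q, 1, 120), rand_seq(30))
    hits2 <- kmer_search(q, db2, quality = strrep("I", nchar(q)), cutoff = 0)
    oracle <- vapply(db2$sequence, oracle_kmer_similarity, numeric(1),
                     query = q)
    expect_equal(hits2$reference_id[1],
                 db2$reference_id[which.max(oracle)])
    expect_equal(max(hits2$similarity), max(oracle))
  })
})

test_that("weighted taxonomy conserves read mass exactly", {
  clusters <- tibble::tibble(sample_id = "s", primer_set = "bacteria_B",
                             cluster_id = 1:3,
                             member_count = c(10L, 5L, 3L))
  hits <- tibble::tibble(
    sample_id = "s", primer_set = "bacteria_B",
    cluster_id = c(1L, 1L, 2L),
    reference_id = c("ra", "rb", "ra"),
    similarity = c(90, 60, 99))
  taxonomy <- tibble::tibble(reference_id = c("ra", "rb"),
                             taxon_path = c("Bacteria;A", "Bacteria;B"))
  prof <- assign_weighted_taxonomy(clusters, hits, taxonomy)
  score <- setNames(prof$score, prof$taxon)
  # cluster 1: 10 reads split 90:60 -> 6 and 4
  expect_equal(score[["Bacteria;A"]], 6 + 5)
  expect_equal(score[["Bacteria;B"]], 4)
  expect_equal(score[["unclassified"]], 3)
  expect_equal(sum(prof$score), 18)
  expect_equal(sum(prof$density), 1, tolerance = 1e-9)
  # single hit takes the whole cluster
  prof1 <- assign_weighted_taxonomy(clusters[1, ], hits[3, ] |>
                                      dplyr::mutate(cluster_id = 1L), taxonomy)
  expect_equal(prof1$score, 10)
  expect_equal(prof1$density, 1)
  # missing taxonomy entry is an error
  expect_error(assign_weighted_taxonomy(
    clusters, dplyr::mutate(hits, reference_id = "zz"), taxonomy),
    "without taxonomy")
})

test_that("density filter keeps the boundary and retains mass", {
  prof <- tibble::tibble(
    sample_id = "s", primer_set = "p",
    taxon = c("a", "b", "c"),
    score = c(989, 10, 1), density = c(0.989, 0.01, 0.001),
    total_reads = 1000L)
  out <- filter_density(prof)
  expect_setequal(out$taxon, c("a", "b", "filtered"))
  expect_equal(out$density[out$taxon == "b"], 0.01)   # >= 1% retained
  expect_equal(sum(out$density), 1)
  expect_equal(sum(out$score), 1000)
  empty <- prof[0, ]
  expect_equal(nrow(filter_density(empty)), 0L)
})

test_that("specificity partitions densities into target and off-target", {
  prof <- tibble::tibble(
    sample_id = "s",
    primer_set = c("streptococcus", "streptococcus", "lactobacillus"),
    taxon = c("Bacteria;Firmicutes;Bacilli;Streptococcus",
              "Bacteria;Fusobacteria", "Bacteria"),
    score = c(90, 10, 50),
    density = c(0.9, 0.1, 1), total_reads = c(100L, 100L, 50L))
  out <- specificity_matrix(prof, the_panel)
  # 23S assays are absent
  expect_false("lactobacillus" %in% out$primer_set)
  strep <- out[out$primer_set == "streptococcus", ]
  expect_equal(strep$on_target, 0.9)
  expect_equal(strep$off_target, 0.1)
})

test_that("FASTQ round trip preserves reads and qualities", {
  withr::local_seed(47)
  reads <- dplyr::bind_rows(mk_read("a", rand_seq(50), "I"),
                            mk_read("b", rand_seq(80), "5"))
  tmp <- tempfile(fileext = ".fastq")
  write_fastq(reads, tmp)
  back <- read_fastq(tmp)
  expect_equal(back$id, reads$id)
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$quality, reads$quality)
})
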