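# Promoter extraction, IUPAC scanning, positional enrichment, density
# classes and spatial maps.

test_that("plus-strand promoter extraction does the coordinate arithmetic", {
  set.seed(1)
  contig <- rand_seq(15000)
  models <- data.frame(gene_id = "g1", seqid = "chr1", start = 10001,
                       end = 12000, strand = "+")   # TSS at 0-based 10000
  pr <- extract_promoters(c(chr1 = contig), models, window = c(-3000, 2000))
  expect_equal(pr$sequence, substr(contig, 7001, 12000))  # slice [7000,12000)
  expect_false(pr$truncated)
  expect_equal(c(pr$win_start, pr$win_end), c(-3000, 2000))
})

test_that("minus-strand promoters are the reverse-complemented mirror", {
  set.seed(2)
  contig <- rand_seq(60)
  models <- data.frame(gene_id = "g1", seqid = "c", start = 10, end = 31,
                       strand = "-")                # TSS at 0-based 30
  pr <- extract_promoters(c(c = contig), models, window = c(-20, 10))
  # rel in [-20,10) covers genomic (20, 41] -> 0-based slice [21, 51)
  expect_equal(pr$sequence, oracle_revcomp(substr(contig, 22, 51)))
  # TSS-relative -10 maps to genomic tss + 10 (0-based 40)
  i <- -10 - pr$win_start + 1
  expect_equal(substr(pr$sequence, i, i),
               ORACLE_COMP[[substr(contig, 41, 41)]])
})

test_that("contig edges truncate with a flag; missing contigs are skipped", {
  contig <- c(c = rand_seq(500))
  models <- data.frame(gene_id = c("g1", "g2"), seqid = c("c", "nope"),
                       start = c(101, 10), end = c(200, 50),
                       strand = "+")
  expect_warning(pr <- extract_promoters(contig, models,
                                         window = c(-3000, 2000)),
                 "missing contig")
  expect_equal(nrow(pr), 1)
  expect_true(pr$truncated)
  expect_equal(pr$win_start, -100)   # only 100 bases upstream exist
  expect_equal(nchar(pr$sequence), pr$win_end - pr$win_start)
})

test_that("GFF3 + FASTA inputs round-trip through extraction", {
  td <- withr::local_tempdir()
  set.seed(3)
  contig <- rand_seq(8000)
  fa <- file.path(td, "genome.fa")
  writeLines(c(">chr1", contig), fa)
  gff <- file.path(td, "genes.gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "test", "gene", "5001", "6000", ".", "+", ".",
                     "ID=gene1", sep = "\t")), gff)
  pr <- extract_promoters(fa, gff, window = c(-1000, 500))
  expect_equal(pr$gene_id, "gene1")
  expect_equal(pr$sequence, substr(contig, 4001, 5500))
})

test_that("scan_motifs finds planted motifs at TSS-relative offsets", {
  win <- c(-1000, 500)
  s <- strsplit(paste(rep("A", 1500), collapse = ""), "")[[1]]
  idx <- -500 - win[1] + 1                     # string index of rel -500
  s[idx:(idx + 5)] <- strsplit("CGTGTG", "")[[1]]
  pr <- data.frame(gene_id = "g1", strand = "+", tss_genomic = NA,
                   win_start = win[1], win_end = win[2], truncated = FALSE,
                   sequence = paste(s, collapse = ""))
  hits <- scan_motifs(pr, data.frame(name = "BRRE", iupac = "CGTGYG"))
  expect_equal(hits$position, -500)
  expect_equal(hits$strand, "+")
})

test_that("palindromic spans are reported once, on the plus strand", {
  pr <- data.frame(gene_id = "g1", strand = "+", tss_genomic = NA,
                   win_start = 0, win_end = 20, truncated = FALSE,
                   sequence = "AAAACACGTGAAAAAAAAAA")  # CACGTG palindromic
  hits <- scan_motifs(pr, data.frame(name = "G-box", iupac = "CACGTG"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "+")
  # N in the sequence never matches
  prn <- pr; prn$sequence <- "AAAACACGNGAAAAAAAAAA"
  expect_equal(nrow(scan_motifs(prn, data.frame(name = "G-box",
                                                iupac = "CACGTG"))), 0)
  expect_error(scan_motifs(pr, data.frame(name = "bad", iupac = "CGTXG")),
               "IUPAC")
  expect_error(scan_motifs(pr, data.frame(name = "GS2", iupac = NA)),
               "without IUPAC")
})

test_that("scanning equals the position-by-position oracle on random input", {
  motifs <- data.frame(name = c("BRRE", "E-box", "DRE/CRT"),
                       iupac = c("CGTGYG", "CANNTG", "RCCGAC"))
  set.seed(4)
  for (rep in 1:10) {
    n <- 20
    pr <- data.frame(gene_id = sprintf("g%02d", 1:n), strand = "+",
                     tss_genomic = NA, win_start = -700, win_end = 300,
                     truncated = FALSE,
                     sequence = vapply(1:n, function(i) rand_seq(1000), ""))
    hits <- scan_motifs(pr, motifs)
    for (i in 1:n) for (m in seq_len(nrow(motifs))) {
      want <- oracle_scan(pr$sequence[i], motifs$iupac[m])
      got <- hits[hits$gene_id == pr$gene_id[i] & hits$motif == motifs$name[m], ]
      expect_setequal(paste(got$position, got$strand),
                      paste(want$position - 700 - 1, want$strand))
    }
  }
})

test_that("hit counts are invariant under strand reversal of promoters", {
  motifs <- data.frame(name = c("BRRE", "as1/ocs"),
                       iupac = c("CGTGYG", "TGACG"))
  set.seed(5)
  pr <- data.frame(gene_id = sprintf("g%02d", 1:15), strand = "+",
                   tss_genomic = NA, win_start = -500, win_end = 500,
                   truncated = FALSE,
                   sequence = vapply(1:15, function(i) rand_seq(1000), ""))
  fwd <- scan_motifs(pr, motifs)
  rev <- pr
  rev$sequence <- vapply(pr$sequence, oracle_revcomp, "", USE.NAMES = FALSE)
  bwd <- scan_motifs(rev, motifs)
  expect_equal(table(fwd$gene_id, fwd$motif), table(bwd$gene_id, bwd$motif))
})

test_that("positional enrichment equals the exact tail-sum oracle", {
  # forced design: all 50 foreground genes hit in-window, 50/1000 background
  genes <- sprintf("g%04d", 1:1000)
  fg <- genes[1:50]
  hits <- data.frame(gene_id = fg, motif = "BRRE", position = -500,
                     strand = "+")
  sc <- positional_enrichment(hits, fg, genes)
  row <- sc[sc$window == "around-500", ]
  expect_equal(row$p, oracle_hyper_tail(50, 50, 1000, 50), tolerance = 1e-9)
  expect_true(row$high_score)
  # foreground == background -> p = 1, score 0
  sc2 <- positional_enrichment(hits, genes, genes)
  expect_true(all(sc2$p == 1))
  expect_true(all(sc2$score == 0))
  expect_error(positional_enrichment(hits, character(0), genes), "empty")
  expect_error(positional_enrichment(hits, "not_there", genes), "subset")
})

test_that("planted positional signal is flagged; control motifs are not", {
  # promoters with BRRE planted around -500 only in foreground genes; an
  # unplanted control motif shows no positional preference
  runs <- 40
  flagged <- control_flagged <- logical(runs)
  for (r in seq_len(runs)) {
    set.seed(1000 + r)
    n <- 60
    pr <- data.frame(gene_id = sprintf("g%02d", 1:n), strand = "+",
                     tss_genomic = NA, win_start = -1200, win_end = 500,
                     truncated = FALSE,
                     sequence = vapply(1:n, function(i) rand_seq(1700), ""))
    fg <- pr$gene_id[1:30]
    for (i in 1:30)
      pr$sequence[i] <- plant_motifs(pr$sequence[i], "CGTGYG", 5,
                                     c(-650, -350), seq_window = c(-1200, 500))
    hits <- scan_motifs(pr, data.frame(name = c("BRRE", "Myb2"),
                                       iupac = c("CGTGYG", "YAACKG")))
    sc <- positional_enrichment(hits, fg, pr$gene_id)
    flagged[r] <- any(sc$high_score[sc$motif == "BRRE"])
    control_flagged[r] <- any(sc$high_score[sc$motif == "Myb2"])
  }
  expect_gte(mean(flagged & !control_flagged), 0.95)
})

test_that("density classes follow the copy-count rule", {
  mk <- function(n) if (n == 0)
    data.frame(gene_id = character(0), motif = character(0),
               position = integer(0), strand = character(0))
  else data.frame(gene_id = "g1", motif = "BRRE",
                  position = seq(-1100, by = 10, length.out = n),
                  strand = "+")
  expect_equal(motif_density(mk(0), "BRRE")$class, "low")
  expect_equal(motif_density(mk(0), "BRRE")$count, 0)
  expect_equal(motif_density(mk(7), "BRRE")$class, "low")
  expect_equal(motif_density(mk(8), "BRRE")$class, "high")
  expect_equal(motif_density(mk(10), "BRRE")$class, "high")
  expect_equal(motif_density(mk(11), "BRRE")$class, "very_high")
  # only in-window hits count
  h <- mk(12); h$position[1:2] <- c(-1300, 600)
  expect_equal(motif_density(h, "BRRE")$count, 10)
  expect_equal(motif_density(h, "BRRE")$class, "high")
})

test_that("spatial map tracks are sorted and consistent with density", {
  set.seed(6)
  hits <- data.frame(gene_id = sample(c("g1", "g2"), 30, TRUE),
                     motif = "BRRE",
                     position = sample(-1500:700, 30), strand = "+")
  sm <- spatial_map(hits, c("g1", "g2", "g3"), window = c(-1200, 500))
  expect_true(all(diff(sm$position[sm$gene_id == "g1"]) >= 0))
  expect_true("g3" %in% attr(sm, "genes"))          # empty track retained
  for (g in c("g1", "g2", "g3")) {
    d <- motif_density(hits[hits$gene_id == g, ], "BRRE", c(-1200, 500))
    expect_equal(sum(sm$gene_id == g), d$count)
  }
  pr <- data.frame(gene_id = c("g1", "g2"))
  expect_message(sm2 <- spatial_map(hits, c("g1", "g2", "g3"),
                                    promoters = pr), "without a promoter")
  expect_false("g3" %in% attr(sm2, "genes"))
})

test_that("density counts nest across windows", {
  set.seed(7)
  pr <- data.frame(gene_id = sprintf("g%02d", 1:10), strand = "+",
                   tss_genomic = NA, win_start = -3000, win_end = 2000,
                   truncated = FALSE,
                   sequence = vapply(1:10, function(i) rand_seq(5000), ""))
  hits <- scan_motifs(pr, data.frame(name = "E-box", iupac = "CANNTG"))
  for (g in pr$gene_id) {
    h <- hits[hits$gene_id == g, ]
    expect_lte(motif_density(h, "E-box", c(-1200, 500))$count,
               motif_density(h, "E-box", c(-3000, 2000))$count)
  }
})
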