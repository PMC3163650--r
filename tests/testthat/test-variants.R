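test_that("gene_model validates its structure", {
  expect_error(gene_model("c", exons = tibble::tibble(start = c(1, 5),
                                                      end = c(10, 20))),
               "non-overlapping")
  expect_error(gene_model("c", exons = tibble::tibble(start = 1, end = 10),
                          cds_start = 1, cds_len = 21),
               "past the spliced mRNA")
  expect_error(gene_model("c", exons = tibble::tibble(start = 1, end = 30),
                          cds_start = 1, cds_len = 8),
               "multiple of 3")
})

test_that("mRNA/genomic mapping round-trips on both strands", {
  m <- toy_model()
  mr <- 1:110
  g <- mrna_to_genomic(m, mr)
  expect_equal(genomic_to_mrna(m, g), mr)
  expect_equal(mrna_to_genomic(m, c(1, 50, 51)), c(101, 150, 201))
  minus <- gene_model("c", strand = "-",
                      exons = tibble::tibble(start = c(101, 201),
                                             end = c(150, 260)))
  expect_equal(mrna_to_genomic(minus, c(1, 60, 61)), c(260, 201, 150))
  expect_equal(genomic_to_mrna(minus, mrna_to_genomic(minus, 1:110)), 1:110)
  expect_true(is.na(genomic_to_mrna(m, 160)))  # intronic
})

test_that("annotation assigns regions, rel positions, UTRs and mRNA offsets", {
  m <- toy_model()
  v <- tibble::tibble(
    type = "SNP",
    genomic_position = c(51, 105, 130, 160, 210, 261, 305),
    hab_allele = "A", lab_allele = "G"
  )
  av <- suppressWarnings(annotate_variants(v, m))
  expect_equal(av$location,
               c("promoter", "exon-1", "exon-1", "intron-1", "exon-2",
                 "DER", "DER"))
  expect_equal(av$rel_position, v$genomic_position - 101L)
  # exon-2 variant: mRNA offset = exon-1 length + offset within exon 2
  expect_equal(av$mrna_position[5], 50L + 10L)
  expect_true(is.na(av$mrna_position[1]))
  # UTR status from the CDS boundaries (CDS = mRNA 11..100)
  expect_equal(av$utr[2], "5'UTR")      # mRNA 5
  expect_true(is.na(av$utr[3]))         # mRNA 30, coding
  expect_equal(suppressWarnings(annotate_variants(v, m))$utr[7], NA_character_)
  expect_warning(annotate_variants(tibble::tibble(type = "SNP",
                                                  genomic_position = 1000), m),
                 "flanking")
  # idempotent and order-invariant
  av2 <- suppressWarnings(annotate_variants(av[sample(nrow(av)), ], m))
  expect_equal(dplyr::arrange(av2, genomic_position), av)
})

test_that("tallies count by type and region with conserved margins", {
  v <- ctsb_variant_table()
  tal <- tally_variants(v)
  total <- function(r, t) tal$n[tal$region == r & tal$type == t]
  expect_equal(total("total", "total"), nrow(v))
  # margins sum to the grand total
  cells <- dplyr::filter(tal, region != "total", type != "total")
  expect_equal(sum(cells$n), nrow(v))
  # empty input gives an all-zero table
  empty <- tally_variants(v[0, ])
  expect_true(all(empty$n == 0))
})

test_that("cluster_scan finds planted windows and is monotone in width", {
  m <- ctsb_gene_model()
  planted <- synth_variant_table(
    m, clusters = tibble::tibble(region = "intron-3", start_rel = 2100,
                                 width = 550, n = 18))
  cs <- cluster_scan(planted, 550)
  expect_equal(cs$n, 18)
  expect_equal(nrow(cluster_scan(planted[1, ], 550)), 1)
  expect_equal(cluster_scan(planted[1, ], 550)$n, 1)
  widths <- c(100, 230, 400, 550, 1000)
  counts <- vapply(widths, function(w) cluster_scan(planted, w)$n[1], integer(1))
  expect_true(all(diff(counts) >= 0))
  # cluster specification wider than its host region is rejected
  expect_error(synth_variant_table(
    m, clusters = tibble::tibble(region = "intron-7", start_rel = 6430,
                                 width = 5000, n = 5)), "wider")
  # empty specification yields an empty annotated table
  expect_equal(nrow(synth_variant_table(m)), 0)
})

test_that("coding consequences translate both alleles", {
  m9 <- gene_model("chrT", exons = tibble::tibble(start = 1, end = 9),
                   promoter_span = 0, der_span = 0,
                   cds_start = 1, cds_len = 9, cds_seq = "TCTGAAGAA")
  vr <- function(pos, hab, lab, type = "SNP") {
    tibble::tibble(type = type, genomic_position = pos,
                   hab_allele = hab, lab_allele = lab)
  }
  # TCT -> CCT at codon position 1: serine in HAB, proline in LAB
  cc1 <- coding_consequence(vr(1, "T", "C"), m9)
  expect_equal(cc1$consequence, "missense(Ser->Pro)")
  # GAA -> GAG third-position wobble: synonymous glutamate
  cc2 <- coding_consequence(vr(6, "A", "G"), m9)
  expect_equal(cc2$consequence, "synonymous")
  expect_equal(cc2$aa_hab, "Glu")
  # GAA -> AAA: glutamic acid to lysine in the LAB allele
  cc3 <- coding_consequence(vr(7, "G", "A"), m9)
  expect_equal(cc3$consequence, "missense(Glu->Lys)")
  # indel in the CDS: frame-affecting, no amino-acid call
  cc4 <- coding_consequence(vr(4, "CT", "", type = "insertion"), m9)
  expect_equal(cc4$consequence, "frame-affecting")
  # outside any exon: non-coding
  m2 <- toy_model(cds_seq = paste(rep("GAA", 30), collapse = ""))
  cc5 <- coding_consequence(vr(160, "A", "G"), m2)
  expect_equal(cc5$consequence, "non-coding")
})

test_that("diff_alleles calls substitutions and indel events", {
  expect_equal(nrow(diff_alleles("ACGTACGTAA", "ACGTACGTAA")), 0)
  one <- diff_alleles("ACGTACGTATCG", "ACGTACGTACCG", offset = 100)
  expect_equal(one$type, "SNP")
  expect_equal(one$genomic_position, 109)
  expect_equal(one$hab_allele, "T")
  expect_equal(one$lab_allele, "C")
  expect_error(diff_alleles("", "ACGT"), "empty")
  expect_error(diff_alleles("ACGX", "ACGT"), "A,C,G,T,N")
  # N columns are skipped
  withN <- diff_alleles("ACGNACGT", "ACGTACGT")
  expect_equal(nrow(withN), 0)
})

test_that("planted variants round-trip through sequence comparison", {
  v <- tibble::tibble(
    type = c("SNP", "insertion", "deletion", "SNP"),
    genomic_position = c(50, 120, 200, 261),
    hab_allele = c("A", "GGC", "", "T"),
    lab_allele = c("C", "", "ATT", "G")
  )
  pair <- synth_allele_pair(v, length_bp = 320, offset = 1, seed = 2)
  called <- diff_alleles(pair$hab, pair$lab, offset = 1)
  expect_equal(nrow(called), 4)
  expect_equal(called$type, v$type)
  expect_equal(called$hab_allele[c(1, 4)], v$hab_allele[c(1, 4)])
  expect_equal(called$lab_allele[3], "ATT")
  # SNP and deletion positions exact
  expect_equal(called$genomic_position[c(1, 3, 4)],
               v$genomic_position[c(1, 3, 4)])
  # the inserted run is recovered up to the usual left-shift ambiguity of
  # gap placement next to homologous bases
  expect_equal(sort(strsplit(called$hab_allele[2], "")[[1]]),
               sort(strsplit("GGC", "")[[1]]))
  expect_lte(abs(called$genomic_position[2] - v$genomic_position[2]), 3)
})

test_that("the synthetic Ctsb table matches its shipped fixture and model", {
  v <- ctsb_variant_table()
  path <- system.file("extdata", "ctsb_variants_synthetic.tsv",
                      package = "divergene")
  file_v <- read_variant_tsv(path)
  expect_equal(nrow(file_v), nrow(v))
  expect_equal(file_v$genomic_position, v$genomic_position)
  expect_equal(file_v$type, v$type)
  expect_equal(file_v$location, v$location)
  # re-annotating against the model reproduces the table's own labels
  re <- annotate_variants(file_v[, c("type", "genomic_position",
                                     "hab_allele", "lab_allele")],
                          ctsb_gene_model())
  expect_equal(re$location, v$location)
  expect_equal(re$rel_position, v$rel_position)
  expect_equal(re$mrna_position, v$mrna_position)
  # every coding SNP in the reconstruction is synonymous
  m <- ctsb_gene_model()
  coding <- dplyr::filter(v, !is.na(mrna_position), is.na(utr), type == "SNP")
  cons <- vapply(seq_len(nrow(coding)), function(i) {
    coding_consequence(coding[i, ], m)$consequence
  }, character(1))
  expect_true(all(cons == "synonymous"))
})

test_that("variant io preserves labels and empty alleles", {
  v <- ctsb_variant_table()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_variant_tsv(v, tmp)
  v2 <- read_variant_tsv(tmp)
  expect_equal(v2$hab_allele, v$hab_allele)
  expect_equal(v2$lab_allele, v$lab_allele)
})
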