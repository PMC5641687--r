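test_that("genotype and item readers round-trip the fixture with types and missingness", {
  gp <- write_geno_fixture(withr::local_tempfile(fileext = ".csv"),
                           geno4_lines)
  geno <- read_genotypes(gp)
  expect_equal(nrow(geno), 4)
  expect_equal(as.character(geno$sex), c("male", "male", "female", "female"))
  expect_equal(geno$rs3, c(0L, NA_integer_, 0L, 1L))

  ip <- write_geno_fixture(withr::local_tempfile(fileext = ".csv"),
                           items4_lines)
  items <- read_items(ip)
  expect_equal(levels(items$wave), c("t1", "t2"))
  expect_true(is.na(items$e1[items$sample_id == "s2" & items$wave == "t1"]))
})

test_that("male diploid dosage is rejected as a coding error", {
  bad <- geno4_lines
  bad[2] <- "s1,male,2,1,0"
  gp <- write_geno_fixture(withr::local_tempfile(fileext = ".csv"), bad)
  expect_error(read_genotypes(gp), "hemizygous")
})

test_that("malformed dosage values are reported with row and column", {
  bad <- geno4_lines
  bad[3] <- "s2,male,x,0,1"
  gp <- write_geno_fixture(withr::local_tempfile(fileext = ".csv"), bad)
  expect_error(read_genotypes(gp), "rs1.*row 2")
})

test_that("VCF input yields hemizygous male dosages", {
  skip_if_not_installed("vcfR")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=X>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tm1\tf1",
    "X\t43402308\trs1\tA\tG\t.\tPASS\t.\tGT\t1\t0/1",
    "X\t43432254\trs2\tA\tG\t.\tPASS\t.\tGT\t0\t1/1")
  vp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, vp)
  g <- read_genotypes_vcf(vp, sex = c(m1 = "male", f1 = "female"))
  expect_equal(g$rs1, c(1L, 1L))
  expect_equal(g$rs2, c(0L, 2L))
  expect_true(all(g$rs1[g$sex == "male"] %in% 0:1))
})

test_that("analytic filter matches a brute-force row scan under MCAR missingness", {
  cfg <- sim_config(sex = "male", n = 1000, traits = "extraversion",
                    waves = 2, missing_rate = 0.05, seed = 99)
  ch <- generate_full_study(cfg)
  flt <- apply_analytic_filter(ch$geno, ch$items)

  # independent oracle: row-by-row scan
  snps <- setdiff(names(ch$geno), c("sample_id", "sex"))
  its <- setdiff(names(ch$items), c("sample_id", "wave"))
  keep <- vapply(ch$geno$sample_id, function(id) {
    g <- ch$geno[ch$geno$sample_id == id, snps]
    i1 <- ch$items[ch$items$sample_id == id & ch$items$wave == "t1", its]
    i2 <- ch$items[ch$items$sample_id == id & ch$items$wave == "t2", its]
    !anyNA(g) && sum(!is.na(i1)) >= 1 && sum(!is.na(i2)) >= 1
  }, logical(1))
  expect_equal(sort(flt$geno$sample_id), sort(names(keep)[keep]))
  expect_equal(flt$log$n[flt$log$reason == "retained"], sum(keep))
})

test_that("single-rule exclusions and empty intersection behave as specified", {
  gp <- write_geno_fixture(withr::local_tempfile(fileext = ".csv"),
                           geno4_lines)
  ip <- write_geno_fixture(withr::local_tempfile(fileext = ".csv"),
                           items4_lines)
  geno <- read_genotypes(gp); items <- read_items(ip)
  flt <- apply_analytic_filter(geno, items)
  # s2 lacks a SNP call; s3 has all wave-2... s3 has e2 observed at t2: kept
  expect_false("s2" %in% flt$geno$sample_id)
  expect_true(all(c("s1", "s3", "s4") %in% flt$geno$sample_id))

  items_bad <- items
  items_bad[items_bad$wave == "t2", c("e1", "e2")] <- NA
  expect_error(apply_analytic_filter(geno, items_bad), "every sample")
})

test_that("MAF counts alleles with sex-appropriate ploidy", {
  # female genotype counts 618/462/100 and male 816/344 from the bundled
  # summary table
  geno <- tibble::tibble(
    sample_id = sprintf("s%04d", 1:(1180 + 1160)),
    sex = factor(rep(c("female", "male"), c(1180, 1160)),
                 levels = c("male", "female")),
    snp = c(rep(0L, 618), rep(1L, 462), rep(2L, 100),
            rep(0L, 816), rep(1L, 344)))
  expect_equal(compute_maf(geno, "snp", "female"), (2 * 100 + 462) / 2360,
               tolerance = 1e-12)
  expect_equal(round(compute_maf(geno, "snp", "female"), 4), 0.2805)
  expect_equal(round(compute_maf(geno, "snp", "male"), 4), round(344 / 1160, 4))
  # folding and label invariance
  flipped <- geno
  flipped$snp <- ifelse(flipped$sex == "male", 1L - flipped$snp,
                        2L - flipped$snp)
  expect_equal(compute_maf(geno, "snp", "both"),
               compute_maf(flipped, "snp", "both"))
  expect_lte(compute_maf(flipped, "snp", "female"), 0.5)

  mono <- tibble::tibble(sample_id = c("a", "b"),
                         sex = factor(c("female", "female"),
                                      levels = c("male", "female")),
                         snp = c(0L, 0L))
  expect_equal(compute_maf(mono, "snp", "female"), 0)
})

test_that("HWE chi-square matches hand-computed expected counts", {
  geno <- tibble::tibble(
    sample_id = sprintf("s%04d", 1:1180),
    sex = factor("female", levels = c("male", "female")),
    snp = c(rep(0L, 618), rep(1L, 462), rep(2L, 100)))
  hw <- hwe_test(geno, "snp")
  # oracle: allele freq q = 0.280508; expected 610.9 / 476.3 / 92.8
  q <- (2 * 100 + 462) / 2360
  expe <- 1180 * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((c(618, 462, 100) - expe)^2 / expe)
  expect_equal(hw$chi2, chi2, tolerance = 1e-12)
  expect_equal(hw$chi2, 1.06, tolerance = 0.01)
  expect_gt(hw$p, 0.05)

  # exact counts at HW proportions give chi2 = 0, p = 1
  ge <- tibble::tibble(sample_id = sprintf("s%03d", 1:100),
                       sex = factor("female", levels = c("male", "female")),
                       snp = c(rep(0L, 36), rep(1L, 48), rep(2L, 16)))
  hw0 <- hwe_test(ge, "snp")
  expect_equal(hw0$chi2, 0, tolerance = 1e-12)
  expect_equal(hw0$p, 1)

  expect_error(hwe_test(geno, "snp", sex_stratum = "male"), "hemizygous")
  expect_lt(hwe_test(geno, "snp", method = "exact")$p, 1)
})

test_that("HWE chi-square test holds its nominal type-I error", {
  set.seed(404)
  reps <- 5000
  n <- 400; q <- 0.3
  probs <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  rej <- 0
  sexcol <- factor(rep("female", n), levels = c("male", "female"))
  for (r in seq_len(reps)) {
    cnt <- as.vector(rmultinom(1, n, probs))
    geno <- tibble::tibble(sample_id = as.character(seq_len(n)),
                           sex = sexcol,
                           snp = rep(0:2, cnt))
    p <- hwe_test(geno, "snp")$p
    if (p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / reps, 0.04)
  expect_lte(rej / reps, 0.06)
})

test_that("LD estimation: self-pair, perfect coupling, and female EM recovery", {
  # self-pair
  geno <- tibble::tibble(sample_id = as.character(1:40),
                         sex = factor(rep("male", 40),
                                      levels = c("male", "female")),
                         a = rep(c(0L, 1L), 20))
  self <- ld_pair(geno, "a", "a")
  expect_equal(self$d_prime, 1)
  expect_equal(self$r, 1)

  # perfect coupling in males
  g2 <- tibble::tibble(sample_id = as.character(1:100),
                       sex = factor(rep("male", 100),
                                    levels = c("male", "female")),
                       a = rep(c(1L, 0L), c(50, 50)),
                       b = rep(c(1L, 0L), c(50, 50)))
  cc <- ld_pair(g2, "a", "b", "male")
  expect_equal(cc$d_prime, 1, tolerance = 1e-9)
  expect_equal(cc$r, 1, tolerance = 1e-9)

  # female EM vs generator truth (haplotype freqs 0.55 0.15 0.05 0.25)
  set.seed(7)
  h <- c(0.55, 0.15, 0.05, 0.25)  # 00 01 10 11
  n <- 5000
  hap <- function(k) cbind(k %/% 2, k %% 2)
  draw <- sample(0:3, 2 * n, TRUE, prob = h)
  h1 <- hap(draw[1:n]); h2 <- hap(draw[(n + 1):(2 * n)])
  gf <- tibble::tibble(sample_id = as.character(1:n),
                       sex = factor(rep("female", n),
                                    levels = c("male", "female")),
                       a = as.integer(h1[, 1] + h2[, 1]),
                       b = as.integer(h1[, 2] + h2[, 2]))
  em <- ld_pair(gf, "a", "b", "female")
  expect_lt(max(abs(em$haplotype_freqs - h)), 0.02)
  expect_equal(sum(em$haplotype_freqs), 1, tolerance = 1e-8)

  # EM equals direct counting when no double heterozygotes exist
  gnd <- gf[!(gf$a == 1 & gf$b == 1), ]
  em2 <- ld_pair(gnd, "a", "b", "female")
  expect_equal(sum(em2$haplotype_freqs), 1, tolerance = 1e-8)
  expect_lte(em2$em_iterations, 3)

  mono <- gf; mono$b <- 0L
  expect_error(ld_pair(mono, "a", "b", "female"), "monomorphic")
})

test_that("endorsement proportions reproduce yes/no count bookkeeping", {
  items <- tibble::tibble(
    sample_id = as.character(seq_len(913)),
    wave = factor("t1", levels = c("t1", "t2")),
    q1 = rep(c(1L, 0L), c(279, 634)))
  et <- endorsement_table(items)
  expect_equal(et$n_yes, 279)
  expect_equal(round(et$prop, 3), 0.306)

  all_yes <- items; all_yes$q1 <- 1L
  expect_equal(endorsement_table(all_yes)$prop, 1)

  items2 <- tibble::tibble(
    sample_id = as.character(seq_len(1042)),
    wave = factor("t2", levels = c("t1", "t2")),
    q1 = rep(c(1L, 0L), c(664, 378)))
  expect_equal(round(endorsement_table(items2)$prop, 3), 0.637)
})

test_that("qc_report records empirical minor allele and writes TSV", {
  cfg <- sim_config(sex = "female", n = 400, traits = "extraversion",
                    waves = 1, seed = 2)
  ch <- generate_full_study(cfg)
  qc <- qc_report(ch$geno, ch$items)
  expect_true(all(qc$snps$maf <= 0.5))
  expect_true(all(!is.na(qc$snps$hwe_p[qc$snps$sex == "female"])))
  out <- withr::local_tempdir()
  paths <- write_qc_report(qc, out)
  expect_true(file.exists(file.path(out, "qc_snps.tsv")))
})
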