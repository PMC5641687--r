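# shared fixtures and small utilities for the test suite

table2_items <- function() {
  readr::read_csv(system.file("extdata", "mpi_item_stats.csv",
                              package = "genefactor"),
                  col_types = "ccccdddd", progress = FALSE)
}

write_geno_fixture <- function(path, lines) {
  writeLines(lines, path)
  path
}

# four-sample genotype CSV: 2 males, 2 females, 3 SNPs
geno4_lines <- c(
  "sample_id,sex,rs1,rs2,rs3",
  "s1,male,0,1,0",
  "s2,male,1,0,NA",
  "s3,female,2,1,0",
  "s4,female,0,2,1")

items4_lines <- c(
  "sample_id,wave,e1,e2",
  "s1,t1,1,0", "s1,t2,0,0",
  "s2,t1,NA,NA", "s2,t2,1,1",
  "s3,t1,0,1", "s3,t2,NA,0",
  "s4,t1,1,1", "s4,t2,0,1")

# deterministic 2x2 table from a target bivariate normal
bvn_table <- function(tau1, tau2, rho, n = 10000) {
  p11 <- genefactor:::bvn_upper(tau1, tau2, rho)
  p1x <- pnorm(tau1, lower.tail = FALSE)
  px1 <- pnorm(tau2, lower.tail = FALSE)
  probs <- c(1 - p1x - px1 + p11, px1 - p11, p1x - p11, p11)
  matrix(round(n * probs), 2, 2)
}

male_ext_config <- function(n = 1160, beta_cross = -0.167,
                            beta_change = 0, waves = 1, seed = 1) {
  sim_config(sex = "male", n = n, traits = "extraversion", waves = waves,
             beta_cross = c(extraversion = beta_cross, neuroticism = 0),
             beta_change = c(extraversion = beta_change, neuroticism = 0),
             seed = seed)
}

cohort_frame <- function(cohort) {
  frame <- items_wide(cohort$items)
  for (s in cohort$config$snps$snp) {
    frame[[s] ] <- cohort$geno[[s]][match(frame$sample_id,
                                          cohort$geno$sample_id)]
  }
  frame
}
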