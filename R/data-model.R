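#' Read a sample-by-SNP genotype table
#'
#' Expects columns `sample_id`, `sex` and one column per SNP holding the
#' minor-allele dosage: males (hemizygous at X-linked loci) in \{0, 1\},
#' females in \{0, 1, 2\}.  Missing calls may be coded by any of
#' `missing_codes`.
#'
#' @param path CSV file path.
#' @param missing_codes character values interpreted as missing.
#' @return tibble with `sample_id` (character), `sex` (factor male/female)
#'   and integer dosage columns.
#' @export
read_genotypes <- function(path, missing_codes = c("NA", "", ".")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = missing_codes, progress = FALSE)
  validate_genotypes(raw, source = path)
}

validate_genotypes <- function(raw, source = "genotype table") {
  need <- c("sample_id", "sex")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop(source, ": missing required column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  snp_cols <- setdiff(names(raw), need)
  if (length(snp_cols) == 0) stop(source, ": no SNP columns", call. = FALSE)
  sex <- tolower(as.character(raw$sex))
  bad_sex <- which(!sex %in% c("male", "female"))
  if (length(bad_sex) > 0) {
    stop(source, ": invalid sex at row ", bad_sex[1], call. = FALSE)
  }
  out <- tibble::tibble(sample_id = as.character(raw$sample_id),
                        sex = factor(sex, levels = c("male", "female")))
  for (s in snp_cols) {
    v <- suppressWarnings(as.numeric(raw[[s]]))
    bad <- which(!is.na(raw[[s]]) & (is.na(v) | !v %in% 0:2))
    if (length(bad) > 0) {
      stop(source, ": non-dosage value '", raw[[s]][bad[1]], "' in column ",
           s, ", row ", bad[1], call. = FALSE)
    }
    male2 <- which(out$sex == "male" & !is.na(v) & v == 2)
    if (length(male2) > 0) {
      stop(source, ": coding error: male sample ", out$sample_id[male2[1]],
           " has diploid dosage 2 in column ", s,
           " (males are hemizygous at X-linked loci)", call. = FALSE)
    }
    out[[s]] <- as.integer(v)
  }
  for (s in snp_cols) {
    if (all(is.na(out[[s]]))) {
      stop(source, ": SNP column ", s, " has no non-missing calls",
           call. = FALSE)
    }
  }
  out
}

#' Read a genotype table from VCF
#'
#' Restricted to biallelic SNPs; dosages count the ALT allele.  Male samples
#' must be hemizygous (haploid genotypes, or homozygous diploid calls which
#' are collapsed to a single allele).  Requires the `vcfR` package.
#'
#' @param path VCF file path.
#' @param sex named character vector mapping sample id to "male"/"female".
#' @return tibble in the same layout as [read_genotypes()].
#' @export
read_genotypes_vcf <- function(path, sex) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_genotypes_vcf() requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    stop("multi-allelic records not supported: ",
         paste(fix[multi, "ID"], collapse = ", "), call. = FALSE)
  }
  samples <- colnames(gt)
  sx <- tolower(sex[samples])
  if (any(is.na(sx))) stop("sex not supplied for sample ",
                           samples[which(is.na(sx))[1]], call. = FALSE)
  dose1 <- function(g, male) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    al <- suppressWarnings(as.integer(al))
    if (any(is.na(al))) return(NA_integer_)
    if (male) {
      if (length(al) == 1) return(al)
      if (al[1] == al[2]) return(al[1])
      stop("heterozygous diploid call for male sample at an X-linked locus",
           call. = FALSE)
    }
    if (length(al) == 1) return(al)  # tolerate haploid female records
    sum(al)
  }
  out <- tibble::tibble(sample_id = samples,
                        sex = factor(sx, levels = c("male", "female")))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("snp", which(is.na(ids) | ids == "."))
  for (i in seq_len(nrow(gt))) {
    out[[ids[i]]] <- vapply(seq_along(samples), function(j) {
      dose1(gt[i, j], sx[j] == "male")
    }, integer(1))
  }
  meta <- tibble::tibble(snp_id = ids,
                         position = as.integer(fix[, "POS"]),
                         allele_major = fix[, "REF"],
                         allele_minor = fix[, "ALT"])
  attr(out, "snp_meta") <- meta
  out
}

#' Read a sample-by-item binary response table
#'
#' Expects columns `sample_id`, `wave` (values `t1`/`t2`) and one 0/1 column
#' per questionnaire item (1 = "yes").
#'
#' @inheritParams read_genotypes
#' @return tibble with `sample_id`, `wave` (factor t1/t2) and integer item
#'   columns.
#' @export
read_items <- function(path, missing_codes = c("NA", "", ".")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = missing_codes, progress = FALSE)
  need <- c("sample_id", "wave")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop(path, ": missing required column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  wv <- tolower(as.character(raw$wave))
  if (any(!wv %in% c("t1", "t2"))) {
    stop(path, ": wave must be t1 or t2 (row ",
         which(!wv %in% c("t1", "t2"))[1], ")", call. = FALSE)
  }
  item_cols <- setdiff(names(raw), need)
  out <- tibble::tibble(sample_id = as.character(raw$sample_id),
                        wave = factor(wv, levels = c("t1", "t2")))
  for (it in item_cols) {
    v <- suppressWarnings(as.numeric(raw[[it]]))
    bad <- which(!is.na(raw[[it]]) & (is.na(v) | !v %in% 0:1))
    if (length(bad) > 0) {
      stop(path, ": non-binary value '", raw[[it]][bad[1]], "' in column ",
           it, ", row ", bad[1], call. = FALSE)
    }
    out[[it]] <- as.integer(v)
  }
  out
}

snp_columns <- function(geno) setdiff(names(geno), c("sample_id", "sex"))
item_columns <- function(items) setdiff(names(items), c("sample_id", "wave"))

#' Apply the analytic-sample rule
#'
#' A sample is retained iff it has complete genotypes across all SNP columns
#' and at least one non-missing personality item at each of the two waves.
#'
#' @param geno genotype tibble ([read_genotypes()] layout).
#' @param items item tibble ([read_items()] layout).
#' @return list with filtered `geno`, `items` and a `log` tibble counting
#'   removals by reason.
#' @export
apply_analytic_filter <- function(geno, items) {
  snps <- snp_columns(geno)
  its <- item_columns(items)
  geno_complete <- geno$sample_id[stats::complete.cases(geno[snps])]
  has_item <- function(wv) {
    sub <- items[items$wave == wv, , drop = FALSE]
    ok <- rowSums(!is.na(sub[its])) >= 1
    sub$sample_id[ok]
  }
  w1 <- has_item("t1"); w2 <- has_item("t2")
  all_ids <- union(geno$sample_id, items$sample_id)
  keep <- intersect(intersect(geno_complete, w1), w2)
  log <- tibble::tibble(
    reason = c("incomplete_genotypes", "no_item_wave1", "no_item_wave2",
               "retained"),
    n = c(sum(!all_ids %in% geno_complete),
          sum(all_ids %in% geno_complete & !all_ids %in% w1),
          sum(all_ids %in% geno_complete & all_ids %in% w1 &
                !all_ids %in% w2),
          length(keep)))
  if (length(keep) == 0) {
    stop("analytic filter removed every sample", call. = FALSE)
  }
  list(geno = geno[geno$sample_id %in% keep, , drop = FALSE],
       items = items[items$sample_id %in% keep, , drop = FALSE],
       log = log)
}

#' Minor allele frequency of one SNP
#'
#' Males contribute one allele, females two; the returned frequency is
#' folded to the minor allele, so it never exceeds 0.5 and is invariant to
#' swapping allele labels.
#'
#' @param geno genotype tibble.
#' @param snp_id SNP column name.
#' @param sex_stratum `"male"`, `"female"` or `"both"`.
#' @return minor allele frequency in `[0, 0.5]`.
#' @export
compute_maf <- function(geno, snp_id,
                        sex_stratum = c("both", "male", "female")) {
  sex_stratum <- match.arg(sex_stratum)
  if (!snp_id %in% names(geno)) stop("unknown SNP: ", snp_id, call. = FALSE)
  g <- geno
  if (sex_stratum != "both") g <- g[g$sex == sex_stratum, , drop = FALSE]
  x <- g[[snp_id]]; sex <- g$sex[!is.na(x)]; x <- x[!is.na(x)]
  if (length(x) == 0) {
    stop("all calls missing for ", snp_id, " in stratum ", sex_stratum,
         call. = FALSE)
  }
  alleles_coded <- sum(ifelse(sex == "male", x, x))
  total <- sum(ifelse(sex == "male", 1, 2))
  f <- alleles_coded / total
  min(f, 1 - f)
}

#' Hardy-Weinberg equilibrium test (females only)
#'
#' X-linked males are hemizygous, so HWE is testable only in the diploid
#' female genotypes.  The default is the 1-df goodness-of-fit chi-square
#' against the expected genotype counts; `method = "exact"` gives the
#' Levene-Haldane exact test (probability-ordering p-value).
#'
#' @inheritParams compute_maf
#' @param method `"chisq"` or `"exact"`.
#' @param sex_stratum must be `"female"`; requesting the male stratum is an
#'   error.
#' @return list with `chi2` (NA for the exact test), `p`, `counts` and
#'   `expected`.
#' @export
hwe_test <- function(geno, snp_id, method = c("chisq", "exact"),
                     sex_stratum = "female") {
  method <- match.arg(method)
  if (!identical(sex_stratum, "female")) {
    stop("HWE is defined for diploid genotypes only; the male (hemizygous) ",
         "stratum is unsupported", call. = FALSE)
  }
  x <- geno[[snp_id]][geno$sex == "female"]
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("no female genotypes for ", snp_id, call. = FALSE)
  n0 <- sum(x == 0); n1 <- sum(x == 1); n2 <- sum(x == 2)
  n <- n0 + n1 + n2
  q <- (2 * n2 + n1) / (2 * n)
  if (q == 0 || q == 1) {
    stop("monomorphic in females: HWE undefined for ", snp_id, call. = FALSE)
  }
  expected <- n * c(`0` = (1 - q)^2, `1` = 2 * q * (1 - q), `2` = q^2)
  if (method == "chisq") {
    chi2 <- sum((c(n0, n1, n2) - expected)^2 / expected)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2 <- NA_real_
    p <- hwe_exact_p(n1, 2 * n2 + n1, n)
  }
  list(chi2 = chi2, p = p, counts = c(`0` = n0, `1` = n1, `2` = n2),
       expected = expected, method = method)
}

# Levene-Haldane exact distribution of the heterozygote count given n
# diploid samples and nA minor alleles; p-value sums probabilities <= that
# of the observed configuration.
hwe_exact_p <- function(n_het, n_minor, n) {
  parity <- n_minor %% 2
  hets <- seq(parity, min(n_minor, 2 * n - n_minor), by = 2)
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - hom_min - h
    lgamma(n + 1) - lgamma(hom_min + 1) - lgamma(h + 1) - lgamma(hom_maj + 1) +
      h * log(2) + lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' Pairwise linkage disequilibrium for X-linked SNPs
#'
#' Haplotype frequencies are counted directly in males (hemizygous, phase
#' known) and estimated by EM over double-heterozygote phase in females; a
#' mixed stratum combines both.  Both D' and r are reported.
#'
#' @inheritParams compute_maf
#' @param snp_a,snp_b SNP column names.
#' @return object of class `ld_result`: list with `d_prime`, `r`, `d`,
#'   `haplotype_freqs` (named `h00`, `h01`, `h10`, `h11` by allele at a/b),
#'   `n_haplotypes`, `em_iterations`.
#' @export
ld_pair <- function(geno, snp_a, snp_b,
                    sex_stratum = c("both", "male", "female")) {
  sex_stratum <- match.arg(sex_stratum)
  if (snp_a == snp_b) {
    p <- compute_maf(geno, snp_a, sex_stratum)
    h <- c(h00 = 1 - p, h01 = 0, h10 = 0, h11 = p)
    return(structure(list(d_prime = 1, r = 1, d = p * (1 - p),
                          haplotype_freqs = h, n_haplotypes = NA_integer_,
                          em_iterations = 0L, sex_stratum = sex_stratum),
                     class = "ld_result"))
  }
  g <- geno
  if (sex_stratum != "both") g <- g[g$sex == sex_stratum, , drop = FALSE]
  ok <- !is.na(g[[snp_a]]) & !is.na(g[[snp_b]])
  g <- g[ok, , drop = FALSE]
  if (nrow(g) == 0) stop("no overlapping non-missing calls", call. = FALSE)
  for (s in c(snp_a, snp_b)) {
    if (length(unique(g[[s]])) < 2) {
      stop("LD undefined: ", s, " is monomorphic in this stratum",
           call. = FALSE)
    }
  }
  a <- g[[snp_a]]; b <- g[[snp_b]]; male <- g$sex == "male"
  # haplotype counts H[i, j]: allele i-1 at snp_a, j-1 at snp_b
  H <- matrix(0, 2, 2)
  for (i in 0:1) for (j in 0:1) H[i + 1, j + 1] <- sum(male & a == i & b == j)
  fem <- cbind(a[!male], b[!male])
  n_hap <- sum(male) + 2 * nrow(fem)
  iter <- 0L
  if (nrow(fem) > 0) {
    h <- rep(0.25, 4)  # h00 h01 h10 h11
    known <- c(H[1, 1], H[1, 2], H[2, 1], H[2, 2])
    repeat {
      iter <- iter + 1L
      e <- known
      for (r in seq_len(nrow(fem))) {
        ga <- fem[r, 1]; gb <- fem[r, 2]
        if (ga == 1 && gb == 1) {
          # double heterozygote: cis (00/11) vs trans (01/10)
          pc <- 2 * h[1] * h[4]; pt <- 2 * h[2] * h[3]
          wc <- pc / (pc + pt)
          e <- e + wc * c(1, 0, 0, 1) + (1 - wc) * c(0, 1, 1, 0)
        } else {
          # at most one heterozygous locus: phase is determined
          aa <- c(rep(0, 2 - ga), rep(1, ga))
          bb <- c(rep(0, 2 - gb), rep(1, gb))
          # phase irrelevant when at most one locus heterozygous
          e <- e + tabulate(1 + aa[1] * 2 + bb[1], 4) +
            tabulate(1 + aa[2] * 2 + bb[2], 4)
        }
      }
      h_new <- e / sum(e)
      if (max(abs(h_new - h)) < 1e-10 || iter >= 500) { h <- h_new; break }
      h <- h_new
    }
    H <- matrix(h * n_hap, 2, 2, byrow = TRUE)
  }
  h <- H / sum(H)
  pa <- h[2, 1] + h[2, 2]; pb <- h[1, 2] + h[2, 2]
  d <- h[2, 2] - pa * pb
  dmax <- if (d >= 0) min(pa * (1 - pb), (1 - pa) * pb) else
    min(pa * pb, (1 - pa) * (1 - pb))
  r <- d / sqrt(pa * (1 - pa) * pb * (1 - pb))
  structure(list(d_prime = if (dmax > 0) abs(d) / dmax else NA_real_,
                 r = r, d = d,
                 haplotype_freqs = c(h00 = h[1, 1], h01 = h[1, 2],
                                     h10 = h[2, 1], h11 = h[2, 2]),
                 n_haplotypes = n_hap, em_iterations = iter,
                 sex_stratum = sex_stratum),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("LD (%s stratum): D' = %.3f, r = %.3f\n", x$sex_stratum,
              x$d_prime, x$r))
  invisible(x)
}

#' Per-item endorsement proportions
#'
#' @param items item tibble.
#' @param wave optional wave filter (`"t1"` or `"t2"`).
#' @return tibble with `item`, `wave`, `n_yes`, `n_no`, `prop` (proportion
#'   "yes" among non-missing responses).
#' @export
endorsement_table <- function(items, wave = NULL) {
  its <- item_columns(items)
  long <- tidyr::pivot_longer(items, cols = dplyr::all_of(its),
                              names_to = "item", values_to = "resp")
  if (!is.null(wave)) long <- long[long$wave == wave, , drop = FALSE]
  long |>
    dplyr::filter(!is.na(.data$resp)) |>
    dplyr::group_by(.data$item, .data$wave) |>
    dplyr::summarise(n_yes = sum(.data$resp == 1),
                     n_no = sum(.data$resp == 0), .groups = "drop") |>
    dplyr::mutate(prop = .data$n_yes / (.data$n_yes + .data$n_no))
}

#' Genotype and phenotype quality-control report
#'
#' Per SNP (by sex stratum): call rate, coded-allele frequency, folded MAF
#' and which allele state is empirically minor, plus the female HWE test.
#' Per item: endorsement proportions by wave.
#'
#' @param geno genotype tibble.
#' @param items item tibble (optional).
#' @return list of tibbles `snps`, `ld`, `items` with class `qc_report`.
#' @export
qc_report <- function(geno, items = NULL) {
  snps <- snp_columns(geno)
  rows <- list()
  for (s in snps) {
    for (sx in c("male", "female")) {
      g <- geno[geno$sex == sx, , drop = FALSE]
      if (nrow(g) == 0) next
      x <- g[[s]]
      nm <- sum(!is.na(x))
      coded <- if (sx == "male") mean(x, na.rm = TRUE) else
        sum(x, na.rm = TRUE) / (2 * nm)
      hw <- if (sx == "female" && nm > 0 &&
                length(unique(x[!is.na(x)])) > 1) {
        hwe_test(geno, s)
      } else NULL
      rows[[length(rows) + 1]] <- tibble::tibble(
        snp = s, sex = sx, n = nrow(g), call_rate = nm / nrow(g),
        coded_allele_freq = coded, maf = min(coded, 1 - coded),
        minor_is_coded = coded <= 0.5,
        hwe_chi2 = if (is.null(hw)) NA_real_ else hw$chi2,
        hwe_p = if (is.null(hw)) NA_real_ else hw$p)
    }
  }
  ld_rows <- list()
  if (length(snps) >= 2) {
    for (i in seq_len(length(snps) - 1)) for (j in (i + 1):length(snps)) {
      for (sx in c("male", "female")) {
        res <- tryCatch(ld_pair(geno, snps[i], snps[j], sx),
                        error = function(e) NULL)
        if (is.null(res)) next
        ld_rows[[length(ld_rows) + 1]] <- tibble::tibble(
          snp_a = snps[i], snp_b = snps[j], sex = sx,
          d_prime = res$d_prime, r = res$r)
      }
    }
  }
  structure(list(snps = dplyr::bind_rows(rows),
                 ld = dplyr::bind_rows(ld_rows),
                 items = if (is.null(items)) NULL else
                   endorsement_table(items)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n== SNPs ==\n"); print(x$snps)
  if (nrow(x$ld) > 0) { cat("== LD ==\n"); print(x$ld) }
  if (!is.null(x$items)) {
    cat("== Items ==\n"); print(x$items, n = 6)
  }
  invisible(x)
}

#' Write a QC report as tab-separated text
#'
#' @param x a `qc_report`.
#' @param dir output directory (created if needed).
#' @return paths written, invisibly.
#' @export
write_qc_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (part in c("snps", "ld", "items")) {
    if (is.null(x[[part]]) || nrow(x[[part]]) == 0) next
    p <- file.path(dir, paste0("qc_", part, ".tsv"))
    readr::write_tsv(x[[part]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
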