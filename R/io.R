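#' Write a genotype matrix as PLINK text PED/MAP
#'
#' The PED phenotype column carries the first trait (PLINK 1/2/-9 coding) or
#' -9 when the sample table has no trait column.  Genotypes are written as
#' two allele letters per SNP; missing genotypes as `0 0`.
#'
#' @param x a `genotype_matrix`
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`
#' @return the prefix, invisibly
#' @export
write_plink <- function(x, prefix) {
  stopifnot(inherits(x, "genotype_matrix"))
  v <- x$variants
  map <- data.frame(chr = v$chr, snp_id = v$snp_id, cm = 0, pos = v$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  traits <- trait_columns(x$samples)
  pheno <- if (length(traits)) x$samples[[traits[1]]] else rep(-9L, nrow(x$geno))
  sex <- x$samples$sex
  if (is.null(sex)) sex <- rep(0L, nrow(x$geno))
  sex[is.na(sex)] <- 0L
  n <- nrow(x$geno); m <- ncol(x$geno)
  # allele pair per genotype code: 0 -> a2/a2, 1 -> a1/a2, 2 -> a1/a1
  lines <- character(n)
  a1 <- v$allele1; a2 <- v$allele2
  for (i in seq_len(n)) {
    g <- x$geno[i, ]
    al1 <- ifelse(is.na(g), "0", ifelse(g >= 1, a1, a2))
    al2 <- ifelse(is.na(g), "0", ifelse(g == 2, a1, a2))
    lines[i] <- paste(x$samples$sample_id[i], x$samples$sample_id[i], 0, 0,
                      sex[i], pheno[i], paste(al1, al2, collapse = " "))
  }
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read PLINK text PED/MAP into a genotype matrix
#'
#' Alleles are recoded to minor-allele copy counts determined from the read
#' sample; at minor-allele frequency exactly 0.5 the alphabetically first
#' allele is counted.  `0 0` genotype fields become missing.
#'
#' @param prefix path prefix of the `.ped`/`.map` pair
#' @return a `genotype_matrix`
#' @export
read_plink <- function(prefix) {
  map_path <- paste0(prefix, ".map"); ped_path <- paste0(prefix, ".ped")
  for (p in c(map_path, ped_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  map_lines <- readLines(map_path)
  map_fields <- strsplit(trimws(map_lines), "\\s+")
  for (i in seq_along(map_fields)) {
    f <- map_fields[[i]]
    if (length(f) != 4)
      stop("malformed MAP line ", i, ": expected 4 fields, got ", length(f), call. = FALSE)
    if (is.na(suppressWarnings(as.numeric(f[4]))))
      stop("malformed MAP line ", i, ": non-numeric position '", f[4], "'", call. = FALSE)
  }
  variants <- data.frame(
    chr = vapply(map_fields, `[`, "", 1),
    snp_id = vapply(map_fields, `[`, "", 2),
    pos = as.integer(vapply(map_fields, function(f) as.numeric(f[4]), 0)),
    stringsAsFactors = FALSE
  )
  m <- nrow(variants)
  ped_lines <- readLines(ped_path)
  n <- length(ped_lines)
  a1m <- matrix("", n, m); a2m <- matrix("", n, m)
  ids <- character(n); sex <- integer(n); pheno <- integer(n)
  legal <- c("A", "C", "G", "T", "0")
  for (i in seq_len(n)) {
    f <- strsplit(trimws(ped_lines[i]), "\\s+")[[1]]
    if (length(f) != 6 + 2 * m)
      stop("malformed PED line ", i, ": expected ", 6 + 2 * m, " fields, got ",
           length(f), call. = FALSE)
    al <- f[-(1:6)]
    if (!all(al %in% legal))
      stop("malformed PED line ", i, ": allele outside {A,C,G,T,0}", call. = FALSE)
    ids[i] <- f[2]
    sex[i] <- suppressWarnings(as.integer(f[5]))
    pheno[i] <- suppressWarnings(as.integer(f[6]))
    a1m[i, ] <- al[seq(1, 2 * m, by = 2)]
    a2m[i, ] <- al[seq(2, 2 * m, by = 2)]
  }
  geno <- matrix(NA_integer_, n, m)
  allele1 <- character(m); allele2 <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1m[, j], a2m[, j])
    obs <- obs[obs != "0"]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2)
      stop("SNP ", variants$snp_id[j], ": more than two alleles observed", call. = FALSE)
    if (length(alleles) == 0) { # all missing
      allele1[j] <- "A"; allele2[j] <- "A"
      next
    }
    if (length(alleles) == 1) alleles <- c(alleles, alleles)
    cnt1 <- sum(obs == alleles[1])
    frac1 <- cnt1 / length(obs)
    # minor allele = the rarer; tie at 0.5 -> alphabetical (alleles sorted)
    minor <- if (frac1 <= 0.5) alleles[1] else alleles[2]
    major <- setdiff(alleles, minor)[1]
    if (is.na(major)) major <- minor
    allele1[j] <- minor; allele2[j] <- major
    miss <- a1m[, j] == "0" | a2m[, j] == "0"
    g <- (a1m[, j] == minor) + (a2m[, j] == minor)
    g[miss] <- NA_integer_
    geno[, j] <- as.integer(g)
  }
  variants$allele1 <- allele1
  variants$allele2 <- allele2
  variants <- variants[, c("chr", "pos", "snp_id", "allele1", "allele2")]
  sex[is.na(sex) | !(sex %in% 1:2)] <- NA_integer_
  samples <- data.frame(sample_id = ids, sex = sex, stringsAsFactors = FALSE)
  if (!all(is.na(pheno)) && any(pheno %in% c(1L, 2L)))
    samples$pheno <- ifelse(pheno %in% c(1L, 2L, -9L), pheno, -9L)
  genotype_matrix(geno, variants, samples)
}

#' Read PLINK binary metadata (BIM/FAM) into variant and sample tables
#'
#' Reads the text metadata half of a PLINK binary fileset.  BED genotype
#' payloads are not parsed; the returned list carries `variants` and
#' `samples` tables only.
#'
#' @param prefix path prefix of the `.bim`/`.fam` pair
#' @return list with `variants` and `samples` data frames
#' @export
read_bim_fam <- function(prefix) {
  bim <- paste0(prefix, ".bim"); fam <- paste0(prefix, ".fam")
  for (p in c(bim, fam)) if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  b <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(b) != 6) stop("malformed BIM: expected 6 columns", call. = FALSE)
  names(b) <- c("chr", "snp_id", "cm", "pos", "allele1", "allele2")
  f <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(f) != 6) stop("malformed FAM: expected 6 columns", call. = FALSE)
  names(f) <- c("fid", "sample_id", "pat", "mat", "sex", "pheno")
  list(variants = b[, c("chr", "pos", "snp_id", "allele1", "allele2")],
       samples = f[, c("sample_id", "sex", "pheno")])
}

#' Write / read a phenotype table (TSV, PLINK status coding)
#'
#' Columns: `sample_id`, `sex`, then one column per trait coded
#' 1 = control, 2 = case, -9 = missing.
#'
#' @param samples sample data frame (as in [genotype_matrix()])
#' @param path output TSV path
#' @return `path` invisibly / the data frame
#' @export
write_phenotypes <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("phenotype table needs a sample_id column", call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Write / read a visit-record table (TSV: patient_id, icd9_code)
#'
#' The number of patients in the underlying cohort is carried in a
#' `# n_patients=` header comment so that marginal prevalences remain
#' computable when some patients have no recorded diagnosis.
#'
#' @param visits visit data frame with `patient_id`, `icd9_code`; may carry
#'   an `n_patients` attribute
#' @param path output TSV path
#' @return `path` invisibly / the data frame (with `n_patients` attribute)
#' @export
write_visits <- function(visits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  np <- attr(visits, "n_patients")
  if (!is.null(np)) writeLines(paste0("# n_patients=", np), con)
  utils::write.table(visits, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_visits
#' @export
read_visits <- function(path) {
  first <- readLines(path, n = 1)
  np <- NULL
  if (grepl("^# n_patients=", first))
    np <- as.integer(sub("^# n_patients=", "", first))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  df$patient_id <- as.character(df$patient_id)
  df$icd9_code <- as.character(df$icd9_code)
  if (!is.null(np)) attr(df, "n_patients") <- np
  df
}
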