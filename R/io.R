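#' Read and write the package's plain-text data formats
#'
#' Pedigrees and phenotypes are CSV; genotypes use a PLINK-.raw-style
#' whitespace table (`FID IID PAT MAT SEX PHENOTYPE` then one column per
#' SNP with codes 0/1/2/NA); sparse symmetric matrices use coordinate text
#' (`row col value` on the upper triangle). Readers validate rather than
#' coerce: malformed rows are errors naming the row, invalid genotype
#' codes are errors naming animal and SNP, and round-tripping write/read
#' reproduces the object.
#'
#' @param ped,geno,phenos,m Objects to write.
#' @param path File path.
#' @name apyss_io
NULL

#' @rdname apyss_io
#' @export
write_pedigree <- function(ped, path) {
  ped <- as_ped(ped)
  out <- data.frame(animal = ped$animal,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam),
                    birth_year = ped$birth_year,
                    genotyped = as.integer(ped$genotyped))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname apyss_io
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) abort(paste0("pedigree file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("animal", "sire", "dam", "birth_year", "genotyped")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) abort(paste0("pedigree header missing column(s): ",
                                     paste(miss, collapse = ", ")))
  by <- suppressWarnings(as.integer(raw$birth_year))
  bad <- which(is.na(by))
  if (length(bad) > 0) abort(paste0("malformed birth_year on data row ", bad[1]))
  gt <- raw$genotyped
  bad <- which(!(gt %in% c("0", "1", "TRUE", "FALSE")))
  if (length(bad) > 0) abort(paste0("malformed genotyped flag on data row ", bad[1]))
  ped_table(tibble::tibble(animal = raw$animal, sire = raw$sire, dam = raw$dam,
                           birth_year = by,
                           genotyped = gt %in% c("1", "TRUE")))
}

#' @rdname apyss_io
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "geno_matrix"))
  M <- geno$M
  df <- data.frame(FID = rownames(M), IID = rownames(M), PAT = 0, MAT = 0,
                   SEX = 0, PHENOTYPE = -9, check.names = FALSE)
  df <- cbind(df, as.data.frame(M, check.names = FALSE))
  utils::write.table(df, path, quote = FALSE, sep = " ", row.names = FALSE)
  invisible(path)
}

#' @rdname apyss_io
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) abort(paste0("genotype file not found: ", path))
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          na.strings = c("NA", "-9.0"))
  lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  miss <- setdiff(lead, names(df))
  if (length(miss) > 0) abort(paste0("genotype header missing column(s): ",
                                     paste(miss, collapse = ", ")))
  snps <- setdiff(names(df), lead)
  if (length(snps) == 0) abort("genotype file has no SNP columns")
  M <- as.matrix(df[snps])
  if (!is.numeric(M)) storage.mode(M) <- "double"
  bad <- which(!(M %in% c(0, 1, 2, NA)))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(M))
    abort(paste0("invalid genotype code ", M[bad[1]], " for animal ",
                 df$IID[rc[1]], " at SNP ", snps[rc[2]]))
  }
  rownames(M) <- as.character(df$IID)
  geno_matrix(M)
}

#' @rdname apyss_io
#' @export
write_phenotypes <- function(phenos, path) {
  readr::write_csv(phenos, path)
  invisible(path)
}

#' @param ped Optional `ped_tbl`; when given, phenotype animals must all
#'   appear in it.
#' @rdname apyss_io
#' @export
read_phenotypes <- function(path, ped = NULL) {
  if (!file.exists(path)) abort(paste0("phenotype file not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    animal = readr::col_character(), value = readr::col_double(),
    .default = readr::col_guess()
  ))
  if (!all(c("animal", "value") %in% names(df))) {
    abort("phenotype file needs columns `animal` and `value`")
  }
  bad <- which(is.na(df$value))
  if (length(bad) > 0) abort(paste0("malformed value on data row ", bad[1]))
  if ("batch" %in% names(df)) df$batch <- factor(df$batch)
  if (!is.null(ped)) {
    ped <- as_ped(ped)
    unknown <- setdiff(df$animal, ped$animal)
    if (length(unknown) > 0) {
      abort(paste0("phenotyped animal not in pedigree: ", unknown[1]))
    }
  }
  df
}

#' @param threshold Recorded drop threshold for the sparse matrix.
#' @rdname apyss_io
#' @export
write_sparse_matrix <- function(m, path, threshold = attr(m, "zero_threshold") %||% 0) {
  sm <- as(as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), "TsparseMatrix")
  keep <- sm@i <= sm@j
  header <- c(paste0("% symmetric coordinate ", nrow(m), " ", threshold))
  lines <- sprintf("%d %d %.17g", sm@i[keep] + 1L, sm@j[keep] + 1L, sm@x[keep])
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname apyss_io
#' @export
read_sparse_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("sparse matrix file not found: ", path))
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  if (hdr[1] != "%" || hdr[2] != "symmetric") abort("not a symmetric coordinate file")
  n <- as.integer(hdr[4])
  threshold <- as.numeric(hdr[5])
  if (length(lines) > 1) {
    df <- utils::read.table(text = lines[-1], col.names = c("i", "j", "x"))
  } else {
    df <- data.frame(i = integer(0), j = integer(0), x = numeric(0))
  }
  m <- Matrix::sparseMatrix(i = df$i, j = df$j, x = df$x, dims = c(n, n),
                            symmetric = TRUE)
  attr(m, "zero_threshold") <- threshold
  m
}

#' Run configuration
#'
#' Assembles (or reads from YAML) the settings of a full scenario run,
#' with the routine defaults: w_a = 0.25, A22^-1 drop threshold 1e-4,
#' PCG tolerance 1e-10, and core fractions 10/30/50%.
#'
#' @param ... Named overrides of the defaults.
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    w_a = 0.25, a22_threshold = 1e-4, pcg_tol = 1e-10, pcg_max_iter = 5000,
    scenarios = c("Random10", "Random30", "Random50", "Offspring10",
                  "OffspringRandom10", "Old10", "Young10", "NormalA"),
    scaling_basis = "all", seed = NULL,
    sigma2_a = 0.3, sigma2_e = 0.7
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown run_config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  if (cfg$w_a < 0 || cfg$w_a > 1) abort("w_a must lie in [0, 1]")
  if (cfg$a22_threshold < 0) abort("a22_threshold must be >= 0")
  structure(cfg, class = "run_config")
}

#' @param path Path to a YAML file whose top-level keys are `run_config`
#'   fields.
#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Write a provenance record for a run
#'
#' JSON with the configuration, seed, package version and R version, so
#' a run can be reproduced from its record.
#'
#' @param path Output path.
#' @param config A `run_config` (or plain list).
#' @param seed The master seed used.
#' @export
write_provenance <- function(path, config, seed = NULL) {
  rec <- list(
    package = "apyss",
    version = as.character(utils::packageVersion("apyss")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(config)
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}
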