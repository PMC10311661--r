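# Readers and writers for the plain-text interchange formats: expression
# matrix TSV, sample-annotation TSV, survival TSV, GMT gene sets, kinome
# CSV, dose-response CSV, and fingerprint text files.

#' Write a cohort to a directory of TSV files
#'
#' Writes `expression.tsv` (genes as rows, sample ids as header),
#' `samples.tsv` (`sample`, `patient`, `condition`) and `survival.tsv`
#' (`patient`, `time`, `event`). Planted truth is not written: files carry
#' only what a real cohort would.
#'
#' @param cohort An `expression_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "expression_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr_path <- file.path(dir, "expression.tsv")
  ann_path <- file.path(dir, "samples.tsv")
  surv_path <- file.path(dir, "survival.tsv")
  expr <- data.frame(gene = rownames(cohort$values), cohort$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(expr, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann <- data.frame(sample = cohort$samples,
                    patient = unname(cohort$patient[cohort$samples]),
                    condition = unname(cohort$condition[cohort$samples]),
                    stringsAsFactors = FALSE)
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$survival, surv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expression = expr_path, samples = ann_path,
              survival = surv_path))
}

#' Read a cohort from a directory of TSV files
#'
#' Counterpart of [write_cohort()]: reconstructs an `expression_cohort`
#' (without planted truth) from `expression.tsv`, `samples.tsv` and
#' `survival.tsv`. Pairing is inferred from shared patient ids between one
#' tumor and one normal sample.
#'
#' @param dir Directory containing the three TSV files.
#' @return An `expression_cohort` (with `truth = NULL`).
#' @export
read_cohort <- function(dir) {
  expr <- utils::read.delim(file.path(dir, "expression.tsv"),
                            check.names = FALSE, stringsAsFactors = FALSE)
  ann <- utils::read.delim(file.path(dir, "samples.tsv"),
                           stringsAsFactors = FALSE)
  surv <- utils::read.delim(file.path(dir, "survival.tsv"),
                            stringsAsFactors = FALSE)
  values <- as.matrix(expr[, -1, drop = FALSE])
  rownames(values) <- expr$gene
  if (anyNA(values)) stop("expression matrix has missing values",
                          call. = FALSE)
  if (any(surv$time <= 0)) stop("survival times must be positive",
                                call. = FALSE)
  tum <- ann[ann$condition == "tumor", ]
  nor <- ann[ann$condition == "normal", ]
  shared <- intersect(tum$patient, nor$patient)
  pairing <- data.frame(
    patient = shared,
    normal = nor$sample[match(shared, nor$patient)],
    tumor = tum$sample[match(shared, tum$patient)],
    stringsAsFactors = FALSE)
  structure(
    list(genes = rownames(values),
         samples = ann$sample,
         values = values[, ann$sample, drop = FALSE],
         condition = stats::setNames(ann$condition, ann$sample),
         patient = stats::setNames(ann$patient, ann$sample),
         pairing = pairing,
         survival = surv,
         truth = NULL,
         params = NULL),
    class = "expression_cohort")
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   then member genes).
#' @return Named list of character vectors; descriptions kept in the
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  attr(sets, "description") <- vapply(fields, `[[`, character(1), 2L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors (or a single
#'   `gene_signature`, written as one line with its derivation summarised
#'   in the description field).
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (inherits(sets, "gene_signature")) {
    d <- sets$derivation
    desc <- sprintf("anchor=%s;corr=%s;fdr=%g;elev_fdr=%g",
                    d$anchor %||% "NA", d$corr_method %||% "NA",
                    d$fdr_cut %||% NA, d$elevation_fdr %||% NA)
    sets <- stats::setNames(list(sets$genes), "signature")
    descriptions <- desc
  }
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write kinome %Ctrl tables
#'
#' CSV with columns `kinase`, `pct_ctrl`, `is_mutant`.
#'
#' @param path File path.
#' @return For the reader, a [kinome_profile()].
#' @export
read_kinome_csv <- function(path) {
  kinome_profile(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_kinome_csv
#' @param profile A [kinome_profile()].
#' @export
write_kinome_csv <- function(profile, path) {
  stopifnot(inherits(profile, "kinome_profile"))
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Read/write dose-response tables
#'
#' CSV with columns `drug`, `dose1`, `dose2` (empty for single agents),
#' `fa`, and optional `flag`.
#'
#' @param path File path.
#' @return For the reader, a [dose_response()].
#' @export
read_dose_response_csv <- function(path) {
  dose_response(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_dose_response_csv
#' @param dr A [dose_response()].
#' @export
write_dose_response_csv <- function(dr, path) {
  utils::write.csv(as.data.frame(dr), path, row.names = FALSE)
  invisible(path)
}

#' Read a ranked-profile TSV (gene, score)
#'
#' @param path File path.
#' @param id Optional profile id (defaults to the file name).
#' @return A [ranked_profile()].
#' @export
read_ranked_profile_tsv <- function(path, id = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  ranked_profile(d$gene, d$score,
                 id = id %||% sub("\\.[^.]*$", "", basename(path)))
}

# Fingerprint text format: one molecule per line, `id<TAB>hex-bitstring`,
# hex encoding the bit vector most-significant-bit-first within each byte.
fp_to_hex <- function(fp) {
  padded <- logical(8L * ceiling(fp$n_bits / 8L))
  padded[fp$bits] <- TRUE
  bytes <- matrix(padded, nrow = 8L)
  vals <- colSums(bytes * 2L^(7:0))
  paste(sprintf("%02x", as.integer(vals)), collapse = "")
}

hex_to_bits <- function(hex, n_bits) {
  vals <- strtoi(substring(hex, seq(1, nchar(hex), 2),
                           seq(2, nchar(hex), 2)), base = 16L)
  # 8 x n_bytes, one column per byte, row 1 = most significant bit
  bitmat <- vapply(vals, function(v) as.integer(intToBits(v))[8:1],
                   integer(8))
  bits <- as.logical(bitmat)  # column-major flatten: byte 1 MSB..LSB, ...
  which(bits[seq_len(n_bits)])
}

#' Write fingerprints as `id<TAB>hex` lines
#'
#' The first line is a header comment `#n_bits=<N>` so the reader can
#' recover the true fingerprint length (hex encoding pads to whole bytes).
#'
#' @param fingerprints List of [fingerprint()]s with equal `n_bits`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fingerprints <- function(fingerprints, path) {
  n_bits <- unique(vapply(fingerprints, `[[`, integer(1), "n_bits"))
  if (length(n_bits) != 1) {
    stop("all fingerprints must share n_bits", call. = FALSE)
  }
  lines <- c(sprintf("#n_bits=%d", n_bits),
             vapply(fingerprints, function(fp) {
               paste(fp$id, fp_to_hex(fp), sep = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- lines[1]
  if (!grepl("^#n_bits=", header)) {
    stop("missing #n_bits header line", call. = FALSE)
  }
  n_bits <- as.integer(sub("^#n_bits=", "", header))
  lapply(lines[-1], function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    fingerprint(id = parts[1], bits = hex_to_bits(parts[2], n_bits),
                n_bits = n_bits)
  })
}
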