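#' Express an allele frequency on the polymorphism's canonical allele
#'
#' Literature samples report whichever of the two alleles the original study
#' coded. The composite index is defined on one canonical allele per
#' polymorphism (the allele in the published loading list, see
#' [dopamine_polymorphisms()]); frequencies reported on the other allele are
#' complemented.
#'
#' @param freq Numeric vector of reported frequencies in `[0, 1]`.
#' @param polymorphism_id Character vector of polymorphism ids (rs numbers or
#'   aliases such as `"DRD2_Taq1A"`), recycled against `freq`.
#' @param reported_allele Character vector naming the allele each `freq`
#'   refers to.
#' @return Numeric vector of frequencies of the canonical allele.
#' @export
#' @examples
#' orient_allele(0.30, "DRD2_Taq1A", "A1")  # already canonical -> 0.30
#' orient_allele(0.30, "DRD2_Taq1A", "A2")  # complement -> 0.70
#' orient_allele(0.45, "DAT1_VNTR", "10R")  # canonical is 9R -> 0.55
orient_allele <- function(freq, polymorphism_id, reported_allele) {
  freq <- as.numeric(freq)
  if (any(!is.finite(freq)) || any(freq < 0 | freq > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  m <- max(length(freq), length(polymorphism_id), length(reported_allele))
  freq <- rep_len(freq, m)
  ids <- resolve_polymorphism(rep_len(as.character(polymorphism_id), m))
  allele <- rep_len(as.character(reported_allele), m)
  i <- match(ids, .poly_table$id)
  canon <- .poly_table$canonical_allele[i]
  other <- .poly_table$other_allele[i]
  out <- ifelse(allele == canon, freq, ifelse(allele == other, 1 - freq, NA_real_))
  bad <- which(is.na(out))
  if (length(bad)) {
    b <- bad[1L]
    stop(sprintf(
      "unknown allele label '%s' for polymorphism %s (expected '%s' or '%s')",
      allele[b], ids[b], canon[b], other[b]), call. = FALSE)
  }
  out
}

#' Orient a whole sample table to canonical alleles
#'
#' Applies [orient_allele()] row-wise to a sample table with columns
#' `polymorphism_id`, `allele`, `freq`, canonicalising both the id and the
#' allele label.
#'
#' @param records Data frame with at least `polymorphism_id`, `allele`,
#'   `freq` columns (the layout written by [write_dataset()]).
#' @return The same data frame with `freq` on the canonical allele,
#'   `allele` set to the canonical label and `polymorphism_id` to the rs id.
#' @export
orient_sample_table <- function(records) {
  need <- c("polymorphism_id", "allele", "freq")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records$freq <- orient_allele(records$freq, records$polymorphism_id,
                                records$allele)
  records$polymorphism_id <- resolve_polymorphism(records$polymorphism_id)
  records$allele <- .poly_table$canonical_allele[
    match(records$polymorphism_id, .poly_table$id)]
  records
}

#' Aggregate sample-level frequencies to one weighted value per population
#'
#' Collapses all samples from the same population to the sample-size-weighted
#' mean frequency per polymorphism, `sum(n_i * f_i) / sum(n_i)`, mirroring
#' how heterogeneous literature samples from one nation are combined. Cells
#' with no sample are missing. An exact duplicate — the same `sample_id`
#' contributing twice to one (population, polymorphism) cell — is an error;
#' resolving near-duplicate study populations (e.g. keeping the largest N)
#' is a curation step that needs bibliographic knowledge and is left to the
#' caller.
#'
#' @param records Data frame of oriented sample records with columns
#'   `sample_id`, `population_id`, `polymorphism_id`, `freq`, `n`
#'   (frequencies already on canonical alleles, see [orient_sample_table()]).
#' @return An object of class `pop_freq_matrix`: a list with `freq`
#'   (populations x polymorphisms matrix of weighted frequencies, `NA` where
#'   unobserved) and `support` (matrix of total N behind each cell, 0 where
#'   unobserved).
#' @export
#' @examples
#' recs <- data.frame(
#'   sample_id = c("s1", "s2"), population_id = "NZ",
#'   polymorphism_id = "rs1800497", freq = c(0.2, 0.4), n = c(100, 300))
#' aggregate_population(recs)$freq["NZ", "rs1800497"]  # 0.35
aggregate_population <- function(records) {
  need <- c("sample_id", "population_id", "polymorphism_id", "freq", "n")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(records)) stop("no records to aggregate", call. = FALSE)
  freq <- as.numeric(records$freq)
  n <- records$n
  if (any(!is.finite(freq)) || any(freq < 0 | freq > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (any(n < 1) || any(n != round(n))) {
    stop("sample sizes must be positive integers", call. = FALSE)
  }
  ids <- resolve_polymorphism(records$polymorphism_id)

  key <- paste(records$population_id, ids, records$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE]
    stop("duplicate sample contribution(s): sample ",
         paste(unique(d$sample_id), collapse = ", "),
         " appears more than once for the same population and polymorphism; ",
         "data from the same study population must enter only once",
         call. = FALSE)
  }

  pops <- sort(unique(as.character(records$population_id)))
  pf <- factor(as.character(records$population_id), levels = pops)
  jf <- factor(ids, levels = .poly_table$id)
  wsum <- tapply(freq * n, list(pf, jf), sum)
  nsum <- tapply(as.numeric(n), list(pf, jf), sum)
  fmat <- wsum / nsum
  nsum[is.na(nsum)] <- 0
  structure(list(freq = fmat, support = nsum), class = "pop_freq_matrix")
}

#' @export
print.pop_freq_matrix <- function(x, ...) {
  cat("Population frequency matrix:", nrow(x$freq), "populations x",
      ncol(x$freq), "polymorphisms\n")
  cat("observed cells:", sum(!is.na(x$freq)), "of", length(x$freq),
      "; total N =", sum(x$support), "\n")
  invisible(x)
}

#' Pivot oriented sample records to a sample-by-polymorphism matrix
#'
#' The sample-level analogue of [aggregate_population()]: each genotyped
#' sample becomes one row, so the index construction can be replicated at
#' the sample level and compared with the population level via Tucker
#' congruence.
#'
#' @inheritParams aggregate_population
#' @return Numeric matrix, rows named by `sample_id`, columns by the nine
#'   canonical polymorphism ids; `NA` where a sample did not report a
#'   polymorphism.
#' @export
sample_frequency_matrix <- function(records) {
  ids <- resolve_polymorphism(records$polymorphism_id)
  samples <- unique(as.character(records$sample_id))
  sf <- factor(as.character(records$sample_id), levels = samples)
  jf <- factor(ids, levels = .poly_table$id)
  if (anyDuplicated(paste(sf, jf, sep = "\r"))) {
    stop("a sample reports the same polymorphism twice", call. = FALSE)
  }
  tapply(as.numeric(records$freq), list(sf, jf), identity)
}

#' Read a sample-level frequency table from CSV
#'
#' Expects the header
#' `sample_id,population_id,continent,polymorphism_id,allele,freq,n`.
#'
#' @param path Path to the CSV file.
#' @return Data frame of sample records.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "population_id", "polymorphism_id", "allele",
            "freq", "n")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("sample table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  d
}
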