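`%||%` <- function(x, y) if (is.null(x)) y else x

#' Canonical variant key
#'
#' Builds the join key used throughout the package: chromosome, position and
#' the *unordered* allele pair. Two records describing the same site with
#' swapped effect/other alleles therefore share a key, which is what lets
#' [harmonize_sumstats()] align effect alleles across studies even when the
#' rsIDs disagree.
#'
#' @param chrom chromosome labels (character or integer).
#' @param pos 1-based positions.
#' @param a1,a2 allele pairs (single upper-case bases).
#' @return character vector of keys, `chrom:pos:min:max`.
#' @export
variant_key <- function(chrom, pos, a1, a2) {
  paste(chrom, pos, pmin(a1, a2), pmax(a1, a2), sep = ":")
}

# unordered allele pair {A,T} or {C,G}: indistinguishable between strands
is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Filtering report of a pipeline object
#'
#' Most readers and filters in the package attach a named list of drop/keep
#' counts to their result; this accessor retrieves it.
#'
#' @param x an object returned by one of the package's readers or filters.
#' @return named list of counts (possibly empty).
#' @export
filter_report <- function(x) attr(x, "report") %||% list()

set_report <- function(x, report) {
  attr(x, "report") <- report
  x
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
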