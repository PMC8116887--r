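#' @title K-mer, stem and root encodings
#'
#' @description
#' A k-mer is a length-`k` window of a read; its *stem* is the middle `k - 2`
#' bases, and its *root* is the canonical form of the stem — the
#' alphabetically smaller of the stem and its reverse complement. All k-mers
#' sharing a root mark the same genomic locus on either strand: a
#' non-palindromic root collects 2 stems x 4 first bases x 4 last bases = 32
#' k-mers, a palindromic one 16.
#'
#' Sequences are packed 2 bits per base with `A = 0, C = 1, G = 2, T = 3`,
#' most-significant base first, so numeric order of codes equals alphabetical
#' order of the decoded strings and canonicalization reduces to an integer
#' `min`. Numeric codes are represented as R doubles and are exact for
#' sequences up to 26 bases (`2 * 26 < 53` mantissa bits); the counting
#' pipeline handles longer k-mers (up to `k = 28`) internally in native
#' 64-bit integers and exposes them as strings.
#'
#' @param seq,kmer,stem,root Character vectors of DNA (`ACGT`) strings.
#' @param code Numeric vector of 2-bit-packed codes.
#' @param k Integer k-mer length.
#' @name kmer_model
NULL

.check_k <- function(k, max = 28L) {
  if (length(k) != 1 || is.na(k) || k < 4 || k > max)
    abort(sprintf("k must be a single integer in [4, %d]", max))
  as.integer(k)
}

#' @describeIn kmer_model Pack a DNA string into its numeric 2-bit code.
#'   Strings containing a non-ACGT character give `NA` (the window is
#'   rejected, not the whole read). Exact up to 26 bases.
#' @return `encode_kmer()`: a numeric vector of codes (`NA` = rejected).
#' @examples
#' encode_kmer("CGTA")        # 108
#' decode_kmer(108, 4)        # "CGTA"
#' revcomp("ATCCG")           # "CGGAT"
#' canonical_root("TACG")     # "CGTA"
#' @export
encode_kmer <- function(seq) {
  if (any(nchar(seq) > 26, na.rm = TRUE))
    abort("numeric codes are exact only up to 26 bases; use string operations")
  cpp_encode_codes(as.character(seq))
}

#' @describeIn kmer_model Inverse of `encode_kmer()`.
#' @export
decode_kmer <- function(code, k) {
  cpp_decode_codes(as.numeric(code), as.integer(k))
}

#' @describeIn kmer_model Reverse complement of DNA strings, or of numeric
#'   codes when `k` is given. An involution: `revcomp(revcomp(x)) == x`.
#' @param x Character or numeric vector.
#' @export
revcomp <- function(x, k = NULL) {
  if (is.character(x)) {
    cpp_revcomp_str(x)
  } else {
    if (is.null(k)) abort("`k` is required for numeric codes")
    encode_kmer(cpp_revcomp_str(decode_kmer(x, k)))
  }
}

#' @describeIn kmer_model Middle `k - 2` bases of each k-mer.
#' @export
stem_of <- function(kmer) {
  n <- nchar(kmer)
  if (any(n < 4)) abort("k-mers must have at least 4 bases")
  substr(kmer, 2L, n - 1L)
}

#' @describeIn kmer_model Canonical root of a stem: the alphabetically
#'   smaller of the stem and its reverse complement. Idempotent, and
#'   identical for a stem and its reverse complement.
#' @export
canonical_root <- function(stem) {
  rc <- cpp_revcomp_str(stem)
  ifelse(.str_le(stem, rc), stem, rc)
}

# locale-independent A<C<G<T comparison via codes (chunked for length > 26)
.str_le <- function(a, b) {
  n <- nchar(a)
  if (all(n <= 26)) return(cpp_encode_codes(a) <= cpp_encode_codes(b))
  out <- logical(length(a))
  for (i in seq_along(a)) {
    ai <- strsplit(a[i], "")[[1]]; bi <- strsplit(b[i], "")[[1]]
    d <- which(ai != bi)
    out[i] <- if (length(d) == 0) TRUE else {
      ord <- c(A = 1, C = 2, G = 3, T = 4)
      ord[[ai[d[1]]]] < ord[[bi[d[1]]]]
    }
  }
  out
}

#' @describeIn kmer_model Root-major integer sort key
#'   `(root_code << 5) | (stem_flag << 4) | (first_base << 2) | last_base`,
#'   where `stem_flag` is 0 when the k-mer's stem already equals its root.
#'   Sorting k-mers by this key groups the up-to-32 k-mers of each root into
#'   one consecutive block `[root * 32, root * 32 + 31]`. Exact for
#'   `k <= 26`; invertible given `k`.
#' @export
sort_key <- function(kmer) {
  k <- unique(nchar(kmer))
  if (length(k) != 1) abort("all k-mers must have equal length")
  .check_k(k, max = 26L)
  root <- encode_kmer(canonical_root(stem_of(kmer)))
  root * 32 + variant_index(kmer)
}

#' @describeIn kmer_model Position of a k-mer among the up-to-32 variants of
#'   its root: the low 5 bits of `sort_key()`, i.e.
#'   `(stem_flag << 4) | (first_base << 2) | last_base`. Fixes the counter
#'   layout of root records (slot `2 v` normal, `2 v + 1` tumoral).
#' @export
variant_index <- function(kmer) {
  n <- nchar(kmer)
  stem <- stem_of(kmer)
  root <- canonical_root(stem)
  flag <- as.integer(stem != root)
  first <- .base_code(substr(kmer, 1L, 1L))
  last <- .base_code(substr(kmer, n, n))
  as.integer(flag * 16L + first * 4L + last)
}

.base_code <- function(b) {
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)[b]
  if (anyNA(code)) abort("non-ACGT base")
  unname(code)
}

#' @describeIn kmer_model All k-mers whose stem canonicalizes to `root`, in
#'   `sort_key()` order: 32 for a non-palindromic root (16 per stem, for the
#'   stem equal to the root and for its reverse complement), 16 when the
#'   stem is its own reverse complement. The 16-variant half of a
#'   palindromic root stays permanently empty in the fixed 64-slot record
#'   layout.
#' @export
kmers_of_root <- function(root) {
  if (length(root) != 1) abort("one root at a time")
  if (!identical(canonical_root(root), root))
    abort("not a canonical root; call canonical_root() first")
  bases <- c("A", "C", "G", "T")
  stems <- c(root, cpp_revcomp_str(root))
  flags <- if (stems[2] == stems[1]) 0L else 0:1
  out <- character(0)
  for (f in flags) {
    for (first in bases) {
      for (last in bases) {
        out <- c(out, paste0(first, stems[f + 1L], last))
      }
    }
  }
  out
}

#' @describeIn kmer_model Every valid length-`k` window of a read, left to
#'   right, as a tibble with 0-based start positions. Windows containing a
#'   non-ACGT character are skipped; reads shorter than `k` give zero rows.
#' @export
kmers_of_read <- function(seq, k) {
  k <- .check_k(k, max = 32L)
  if (length(seq) != 1) abort("one read at a time")
  n <- nchar(seq)
  if (is.na(seq) || n < k) return(tibble(pos = integer(0), kmer = character(0)))
  win <- substring(toupper(seq), 1:(n - k + 1), k:n)
  ok <- !grepl("[^ACGT]", win)
  tibble(pos = which(ok) - 1L, kmer = win[ok])
}
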