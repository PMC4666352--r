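#' Allowed base triads per intrastrand triplex class
#'
#' Each intrastrand triplex class permits a fixed set of stacked base triads
#' `(a, b, c)`, read at one stack position as the letter of stemA, the
#' (antiparallel) letter of stemB and the letter of stemC:
#'
#' * Class I (purine motif, Hoogsteen stem 5'): `A-A-T`, `G-G-C`, `T-A-T`
#' * Class II (purine motif, pyrimidine stem 5'): `C-G-G`, `T-A-A`, `T-A-T`
#' * Class III (pyrimidine motif): `A-T-T`, `G-C-C`
#' * Class IV (pyrimidine motif): `T-T-A`, `C-C-G`
#'
#' "Mixed stems" are allowed: any triad of the class may occur at any stack
#' position, e.g. a class II stem dominated by `C-G-G` may contain `T-A-A` or
#' `T-A-T` positions.
#'
#' @param classes Character vector, subset of `c("I","II","III","IV")`.
#' @return A tibble with columns `class`, `a`, `b`, `c`, one row per allowed
#'   triad.
#' @export
triplet_table <- function(classes = c("I", "II", "III", "IV")) {
  classes <- match_classes(classes)
  tab <- tibble::tribble(
    ~class, ~a,  ~b,  ~c,
    "I",    "A", "A", "T",
    "I",    "G", "G", "C",
    "I",    "T", "A", "T",
    "II",   "C", "G", "G",
    "II",   "T", "A", "A",
    "II",   "T", "A", "T",
    "III",  "A", "T", "T",
    "III",  "G", "C", "C",
    "IV",   "T", "T", "A",
    "IV",   "C", "C", "G"
  )
  tab[tab$class %in% classes, ]
}

TRIPLEX_CLASSES <- c("I", "II", "III", "IV")

match_classes <- function(classes) {
  classes <- as.character(classes)
  bad <- setdiff(classes, TRIPLEX_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown triplex class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unique(classes)
}

#' Test one base triad against a triplex class
#'
#' @param triplex_class One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param a,b,c Single bases (stemA, stemB, stemC letters at one stack
#'   position). Any `N` makes the triad invalid.
#' @return `TRUE` iff `(a, b, c)` is an allowed triad of the class.
#' @examples
#' triplet_valid("I", "G", "G", "C")  # TRUE
#' triplet_valid("II", "C", "G", "G") # TRUE
#' triplet_valid("I", "G", "G", "T")  # FALSE
#' @export
triplet_valid <- function(triplex_class, a, b, c) {
  tab <- triplet_table(triplex_class)
  any(tab$a == a & tab$b == b & tab$c == c)
}

# Integer coding used by the compiled scanner: A=0 C=1 G=2 T=3 N=4.
DNA_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L)

encode_dna <- function(seq) {
  codes <- DNA_CODE[strsplit(seq, "", fixed = TRUE)[[1]]]
  if (anyNA(codes)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  unname(codes)
}

# 4 x 5 x 5 x 5 logical lookup: valid[class, a+1, b+1, c+1]
triad_lookup <- function() {
  tab <- triplet_table()
  arr <- array(FALSE, dim = c(4L, 5L, 5L, 5L))
  cls <- match(tab$class, TRIPLEX_CLASSES)
  arr[cbind(cls, DNA_CODE[tab$a] + 1L, DNA_CODE[tab$b] + 1L,
            DNA_CODE[tab$c] + 1L)] <- TRUE
  arr
}

# mismatch allowance as a pure function of stem length
mismatch_allowance <- function(stem_len, mismatch = TRUE) {
  if (!mismatch) return(rep(0L, length(stem_len)))
  ifelse(stem_len >= 7L, 1L, 0L)
}
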