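# Internal base encoding. Bases are stored as integer codes 1:4 (A,C,G,T);
# consensus sets are stored as bitmasks over bits 1,2,4,8 so a tied consensus
# is a single integer and "base sets intersect" is a bitwAnd.

.datatable.aware <- TRUE

.BASES <- c("A", "C", "G", "T")
.BITS <- c(1L, 2L, 4L, 8L)

base_to_code <- function(base) {
  if (is.numeric(base)) {
    code <- as.integer(base)
  } else {
    code <- match(toupper(as.character(base)), .BASES)
  }
  code
}

code_to_base <- function(code) .BASES[code]

code_to_bit <- function(code) .BITS[code]

# "A/T" style label for a consensus bitmask
mask_to_label <- function(mask) {
  vapply(mask, function(m) {
    paste(.BASES[bitwAnd(m, .BITS) > 0L], collapse = "/")
  }, character(1))
}

# expand a bitmask into its base codes
mask_to_codes <- function(mask) which(bitwAnd(mask, .BITS) > 0L)

# bitwAnd() drops dim attributes; keep them
bitand_mat <- function(m, v) {
  out <- bitwAnd(m, v)
  dim(out) <- dim(m)
  out
}

# round half away from zero (2.6 -> 3, 2.5 -> 3); base round() is banker's
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
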