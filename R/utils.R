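# Internal sequence utilities shared across modules.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

.bhlh_env <- new.env(parent = emptyenv())

# PAM250 extended with X (neutral, 0) and * (harshly penalized) so that
# translated frames containing stops or fuzzy codons can be scored directly.
pam250_matrix <- function() {
  if (!is.null(.bhlh_env$pam250)) return(.bhlh_env$pam250)
  m <- get_pam250_raw()
  keep <- intersect(rownames(m), c(AA20, "X", "*"))
  m <- m[keep, keep, drop = FALSE]
  if (!"X" %in% rownames(m)) {
    m <- rbind(cbind(m, X = 0L), X = 0L)
  } else {
    m["X", ] <- 0L; m[, "X"] <- 0L
  }
  if (!"*" %in% rownames(m)) {
    m <- rbind(cbind(m, `*` = -8L), `*` = -8L)
  }
  m["*", ] <- -8L; m[, "*"] <- -8L
  .bhlh_env$pam250 <- m
  m
}

get_pam250_raw <- function() {
  e <- new.env()
  utils::data("PAM250", package = "Biostrings", envir = e)
  e$PAM250
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Sum of PAM250 scores over two equal-length ungapped strings.
pam_score <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("pam_score: unequal lengths")
  if (nchar(a) == 0L) return(0L)
  m <- pam250_matrix()
  ai <- split_chars(a); bi <- split_chars(b)
  ai[!ai %in% rownames(m)] <- "X"
  bi[!bi %in% rownames(m)] <- "X"
  sum(m[cbind(ai, bi)])
}

# Per-position PAM250 scores for two equal-length character vectors.
pam_score_vec <- function(ai, bi) {
  m <- pam250_matrix()
  ai[!ai %in% rownames(m)] <- "X"
  bi[!bi %in% rownames(m)] <- "X"
  unname(m[cbind(ai, bi)])
}

pam_self_score <- function(a) pam_score(a, a)

#' Reverse-complement a DNA string
#'
#' @param dna A single DNA string over `A`, `C`, `G`, `T`, `N`.
#' @return The reverse complement as a single string.
#' @keywords internal
revcomp <- function(dna) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", dna)
  paste(rev(split_chars(comp)), collapse = "")
}

genetic_code <- function() {
  if (!is.null(.bhlh_env$gcode)) return(.bhlh_env$gcode)
  gc <- Biostrings::GENETIC_CODE
  .bhlh_env$gcode <- gc
  gc
}

# Translate a DNA string starting in-frame at position 1; trailing partial
# codon dropped; stops rendered "*"; codons containing N rendered "X".
translate_dna <- function(dna) {
  n <- nchar(dna)
  naa <- n %/% 3L
  if (naa == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = naa)
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(genetic_code()[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Reverse table from amino acid to codons, for reverse translation.
codons_for_aa <- function() {
  if (!is.null(.bhlh_env$rev_gcode)) return(.bhlh_env$rev_gcode)
  gc <- genetic_code()
  .bhlh_env$rev_gcode <- split(names(gc), unname(gc))
  .bhlh_env$rev_gcode
}

is_dna_string <- function(x) grepl("^[ACGTN]*$", x)
is_protein_string <- function(x) grepl("^[ARNDCQEGHILKMFPSTWYVX*-]*$", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
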