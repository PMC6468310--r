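## Pluggable RNA folding engines behind a single "MFE of string" contract.
## "builtin" is a fast weighted base-pair-maximisation folder (compiled, used
## by default so profiles and the simulator's rejection loops stay cheap);
## "rnafold" shells out to ViennaRNA's RNAfold for full nearest-neighbour
## thermodynamics at 37 C. Any function(seqs) -> energies can be plugged in.

resolve_engine <- function(engine) {
  if (is.function(engine)) return(engine)
  engine <- match.arg(engine, c("builtin", "rnafold"))
  switch(engine,
         builtin = function(seqs) vapply(seqs, .mfe_nussinov, numeric(1),
                                         USE.NAMES = FALSE),
         rnafold = rnafold_mfe)
}

#' Minimum free energy of RNA sequences
#'
#' @param seqs character vector of nucleotide sequences (T is read as U).
#' @param engine `"builtin"` (compiled weighted base-pair minimiser),
#'   `"rnafold"` (ViennaRNA RNAfold at 37 C, must be on the PATH), or a
#'   function mapping a character vector of sequences to a numeric vector of
#'   energies in kcal/mol.
#' @return numeric vector of MFE values (kcal/mol), each `<= 0`.
#' @export
mfe <- function(seqs, engine = "builtin") {
  fn <- resolve_engine(engine)
  fn(normalize_seq(seqs))
}

rnafold_mfe <- function(seqs) {
  if (Sys.which("RNAfold") == "")
    stop2("RNAfold not found on PATH; install ViennaRNA or use engine = 'builtin'")
  if (length(seqs) == 0L) return(numeric(0))
  input <- as.vector(rbind(paste0(">w", seq_along(seqs)), chartr("T", "U", seqs)))
  out <- system2("RNAfold", c("--noPS"), input = input, stdout = TRUE)
  elines <- grep("\\(\\s*-?[0-9.]+\\)\\s*$", out, value = TRUE)
  if (length(elines) != length(seqs))
    stop2("RNAfold returned ", length(elines), " energies for ",
          length(seqs), " sequences")
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", elines))
}

#' Sliding-window RNA folding-energy profile
#'
#' Slides a fixed-width window along a nucleotide sequence and records the
#' minimum free energy of each window, giving
#' `floor((len - window)/step) + 1` values for sequences at least one window
#' long and an empty profile (with a warning) otherwise.
#'
#' @param seq nucleotide string.
#' @param window window width in nt (default 40).
#' @param step window step in nt (default 1).
#' @param engine see [mfe()].
#' @param anchor optional free-text description of the region the profile was
#'   taken from (e.g. `"-100..+50 of START"`).
#' @return an object of class `folding_profile` with elements `energies`,
#'   `window`, `step`, `anchor`.
#' @export
folding_profile <- function(seq, window = 40L, step = 1L, engine = "builtin",
                            anchor = NULL) {
  s <- normalize_seq(seq)
  n <- nchar(s)
  if (n < window) {
    warning(sprintf("sequence (%d nt) shorter than window (%d nt): empty profile",
                    n, window))
    energies <- numeric(0)
  } else {
    m <- (n - window) %/% step + 1L
    starts <- (seq_len(m) - 1L) * step
    windows <- substring(s, starts + 1L, starts + window)
    energies <- resolve_engine(engine)(windows)
  }
  structure(list(energies = energies, window = as.integer(window),
                 step = as.integer(step), anchor = anchor %||% ""),
            class = "folding_profile")
}

#' @export
print.folding_profile <- function(x, ...) {
  cat(sprintf("<folding_profile> %d windows (%d nt, step %d)%s\n",
              length(x$energies), x$window, x$step,
              if (nzchar(x$anchor)) paste0(" @ ", x$anchor) else ""))
  if (length(x$energies))
    cat(sprintf("  energies: mean %.2f, range [%.2f, %.2f] kcal/mol\n",
                mean(x$energies), min(x$energies), max(x$energies)))
  invisible(x)
}

#' @export
length.folding_profile <- function(x) length(x$energies)

#' Pearson similarity of two folding profiles
#'
#' Profiles are aligned at their anchor (both are computed over regions
#' positioned identically relative to the start codon) and truncated to the
#' shorter length; the Pearson correlation of the aligned energy vectors is
#' returned. Undefined (NA, with a warning suppressed for batch use) when
#' fewer than 3 windows align or either vector is constant.
#'
#' @param p1,p2 `folding_profile` objects.
#' @return correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
profile_similarity <- function(p1, p2) {
  e1 <- p1$energies; e2 <- p2$energies
  m <- min(length(e1), length(e2))
  if (m < 3L) return(NA_real_)
  e1 <- e1[seq_len(m)]; e2 <- e2[seq_len(m)]
  if (sd(e1) == 0 || sd(e2) == 0) return(NA_real_)
  cor(e1, e2)
}

#' Position-specific mean absolute folding-energy margin
#'
#' For aligned lists of upstream-gene and downstream-gene profiles (one of
#' each per gene pair), computes at every aligned window position the mean
#' over pairs of `|E5 - E3|`. This is the position-wise group margin used to
#' compare co-transcribed and independent pairs along the 5' region.
#'
#' @param profiles5,profiles3 lists of `folding_profile`s of equal length.
#' @return data.frame with `position` (0-based window start index) and
#'   `mean_abs_margin` (kcal/mol).
#' @export
position_margin_profile <- function(profiles5, profiles3) {
  if (length(profiles5) == 0L || length(profiles5) != length(profiles3))
    stop2("need equally many upstream and downstream profiles, at least one pair")
  m <- min(vapply(c(profiles5, profiles3), function(p) length(p$energies),
                  integer(1)))
  if (m == 0L) stop2("a profile is empty; no aligned positions")
  mat <- matrix(vapply(seq_along(profiles5), function(i)
    abs(profiles5[[i]]$energies[seq_len(m)] - profiles3[[i]]$energies[seq_len(m)]),
    numeric(m)), nrow = m)
  data.frame(position = seq_len(m) - 1L,
             mean_abs_margin = rowMeans(mat))
}
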