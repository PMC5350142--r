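# Oligonucleotide melting temperature and primer quality heuristics.
#
# Short primers (<= 14 nt) use the Wallace rule; longer primers use the
# unified nearest-neighbor parameters of SantaLucia (1998) at fixed default
# conditions (50 mM Na+, 0.25 uM oligo). These are screening estimates for
# primer QC, not calibrated predictions for any particular PCR buffer.

# SantaLucia 1998 unified NN parameters: dH kcal/mol, dS cal/(mol K)
NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)

tm_wallace <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
}

tm_nearest_neighbor <- function(seq, na_molar = 0.05, oligo_molar = 0.25e-6) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  steps <- paste0(b[-n], b[-1])
  dh <- sum(NN_DH[steps])
  ds <- sum(NN_DS[steps])
  # duplex initiation, per terminal base pair
  for (term in b[c(1, n)]) {
    if (term %in% c("G", "C")) {
      dh <- dh + 0.1; ds <- ds - 2.8
    } else {
      dh <- dh + 2.3; ds <- ds + 4.1
    }
  }
  ds <- ds + 0.368 * (n - 1) * log(na_molar)
  1000 * dh / (ds + 1.987 * log(oligo_molar / 4)) - 273.15
}

#' Melting temperature of a concrete oligonucleotide
#'
#' Wallace rule (2 degC per A/T + 4 degC per G/C) for oligos of 14 nt or
#' fewer, nearest-neighbor thermodynamics (SantaLucia 1998 unified
#' parameters) otherwise.
#'
#' @param seq A/C/G/T string.
#' @param na_molar Monovalent cation concentration (mol/L).
#' @param oligo_molar Oligonucleotide concentration (mol/L).
#' @return Temperature in degrees Celsius.
#' @export
oligo_tm <- function(seq, na_molar = 0.05, oligo_molar = 0.25e-6) {
  seq <- toupper(seq)
  if (iupac_degeneracy(seq) != 1L) {
    stop("oligo_tm() needs a concrete A/C/G/T sequence; see primer_tm_range()",
         call. = FALSE)
  }
  if (nchar(seq) <= 14) tm_wallace(seq)
  else tm_nearest_neighbor(seq, na_molar, oligo_molar)
}

#' Melting-temperature range of a degenerate primer
#'
#' Computes the Tm of every concrete expansion (up to `cap` variants) and
#' returns the min/max. Above the cap, only the per-position most and least
#' stabilizing expansions are evaluated.
#'
#' @inheritParams oligo_tm
#' @param cap Maximum number of expansions to enumerate exhaustively.
#' @return Named numeric vector `c(tm_min = , tm_max = )`.
#' @export
primer_tm_range <- function(seq, na_molar = 0.05, oligo_molar = 0.25e-6,
                            cap = 1024L) {
  seq <- toupper(seq)
  if (iupac_degeneracy(seq) <= cap) {
    tms <- vapply(iupac_expand(seq, cap), oligo_tm, numeric(1),
                  na_molar = na_molar, oligo_molar = oligo_molar)
    return(c(tm_min = min(tms), tm_max = max(tms)))
  }
  pick <- function(order) {
    vapply(iupac_masks(seq), function(m) {
      hit <- order[bitwAnd(IUPAC_MASK[order], m) > 0L]
      hit[1]
    }, character(1))
  }
  weak <- paste(pick(c("A", "T", "C", "G")), collapse = "")
  strong <- paste(pick(c("G", "C", "T", "A")), collapse = "")
  c(tm_min = oligo_tm(weak, na_molar, oligo_molar),
    tm_max = oligo_tm(strong, na_molar, oligo_molar))
}

# Complementarity indicator between position vectors of two masks
comp_hits <- function(ma, mb) bitwAnd(ma, COMP_MASK[mb]) > 0L

# Scan all ungapped antiparallel alignments of a against b; returns the
# longest contiguous complementary run and the longest run touching either
# 3' terminus, with the offending alignment recorded.
dimer_scan <- function(a, b) {
  ma <- iupac_masks(a)
  mb_rev <- rev(iupac_masks(b))   # b read 3'->5' against a read 5'->3'
  na <- length(ma); nb <- length(mb_rev)
  best <- list(run = 0L, run_3p = 0L, detail = NULL)
  for (shift in (-(nb - 1L)):(na - 1L)) {
    ia <- max(1L, shift + 1L):min(na, shift + nb)
    ib <- ia - shift
    hits <- comp_hits(ma[ia], mb_rev[ib])
    if (!any(hits)) next
    r <- rle(hits)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      len <- r$lengths[k]
      # 3' terminus of a is ma[na]; 3' terminus of b is mb_rev[1]
      touch3p <- (ia[ends[k]] == na) || (ib[starts[k]] == 1L)
      if (len > best$run ||
          (touch3p && len > best$run_3p)) {
        if (len > best$run) best$run <- len
        if (touch3p && len > best$run_3p) best$run_3p <- len
        best$detail <- sprintf("shift %d, %d complementary bp at %d..%d",
                               shift, len, ia[starts[k]], ia[ends[k]])
      }
    }
  }
  best
}

# Exhaustive stem-loop scan: any stem of >= stem_min complementary bp
# enclosing a loop of >= loop_min nt flags a hairpin. A stem anchored at
# (i, j) pairs i+t with j-t (antiparallel) for t = 0..s-1, leaving a loop of
# j - i - 2s + 1 unpaired nt.
hairpin_scan <- function(seq, stem_min = 4L, loop_min = 3L) {
  m <- iupac_masks(seq)
  n <- length(m)
  min_span <- 2L * stem_min + loop_min  # j - i + 1 at the tightest
  if (n < min_span) return(list(flag = FALSE, detail = NULL))
  for (i in 1:(n - min_span + 1L)) {
    for (j in (i + min_span - 1L):n) {
      s <- 0L
      while (i + s < j - s && comp_hits(m[i + s], m[j - s])) s <- s + 1L
      # shrink the stem if needed to keep the loop open
      s <- min(s, (j - i + 1L - loop_min) %/% 2L)
      if (s >= stem_min) {
        return(list(flag = TRUE,
                    detail = sprintf("stem %d bp: %d..%d with %d..%d",
                                     s, i, i + s - 1L, j - s + 1L, j)))
      }
    }
  }
  list(flag = FALSE, detail = NULL)
}

#' Primer quality screen
#'
#' Reports degeneracy, the Tm range over all concrete expansions, and
#' heuristic hairpin / self-dimer / cross-dimer flags for a (possibly
#' degenerate) primer. A dimer is flagged on a contiguous complementary run
#' of at least `dimer_run` bp in any ungapped antiparallel alignment, or of
#' at least `dimer_run_3p` bp covering a 3' terminus. A hairpin is flagged
#' on a stem of at least `stem_min` complementary bp enclosing a loop of at
#' least `loop_min` nt.
#'
#' @param seq Primer sequence (IUPAC), length 10-40 nt.
#' @param partner Optional partner primer for the cross-dimer check.
#' @param stem_min,loop_min Hairpin thresholds (bp, nt).
#' @param dimer_run,dimer_run_3p Dimer run thresholds (bp).
#' @inheritParams oligo_tm
#' @return A list of class `primer_qc` with fields `degeneracy`, `tm_min`,
#'   `tm_max`, `hairpin_flag`, `self_dimer_flag`, `cross_dimer_flag`, and a
#'   `detail` list recording each offending sub-alignment.
#' @export
primer_qc <- function(seq, partner = NULL,
                      stem_min = 4L, loop_min = 3L,
                      dimer_run = 8L, dimer_run_3p = 5L,
                      na_molar = 0.05, oligo_molar = 0.25e-6) {
  seq <- toupper(seq)
  if (nchar(seq) < 10 || nchar(seq) > 40) {
    stop("primer length ", nchar(seq), " outside the supported 10-40 nt range",
         call. = FALSE)
  }
  tm <- primer_tm_range(seq, na_molar, oligo_molar)
  hp <- hairpin_scan(seq, stem_min, loop_min)
  sd <- dimer_scan(seq, seq)
  out <- list(
    degeneracy = iupac_degeneracy(seq),
    tm_min = unname(tm["tm_min"]),
    tm_max = unname(tm["tm_max"]),
    hairpin_flag = hp$flag,
    self_dimer_flag = sd$run >= dimer_run || sd$run_3p >= dimer_run_3p,
    cross_dimer_flag = NA,
    detail = list(hairpin = hp$detail, self_dimer = sd$detail,
                  cross_dimer = NULL)
  )
  if (!is.null(partner)) {
    cd <- dimer_scan(seq, toupper(partner))
    out$cross_dimer_flag <- cd$run >= dimer_run || cd$run_3p >= dimer_run_3p
    out$detail$cross_dimer <- cd$detail
  }
  structure(out, class = "primer_qc")
}

#' @export
print.primer_qc <- function(x, ...) {
  cat(sprintf("primer QC: degeneracy %d, Tm %.1f-%.1f degC\n",
              x$degeneracy, x$tm_min, x$tm_max))
  cat(sprintf("  hairpin: %s  self-dimer: %s  cross-dimer: %s\n",
              x$hairpin_flag, x$self_dimer_flag, x$cross_dimer_flag))
  invisible(x)
}
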