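#' @importFrom Biostrings DNAString reverseComplement readDNAStringSet
NULL

# Unified nearest-neighbor parameters (SantaLucia & Hicks 2004).
# dH in kcal/mol, dS in cal/mol/K, for 5'->3' dinucleotide stacks on the
# top strand of a Watson-Crick duplex.  The six stacks missing from the
# table are looked up through their reverse complement.
.nnTable <- data.frame(
  stack = c("AA", "AT", "TA", "CA", "GT", "CT", "GA", "CG", "GC", "GG"),
  dH = c(-7.9, -7.2, -7.2, -8.5, -8.4, -7.8, -8.2, -10.6, -9.8, -8.0),
  dS = c(-22.2, -20.4, -21.3, -22.7, -22.4, -21.0, -22.2, -27.2, -24.4,
         -19.9),
  stringsAsFactors = FALSE)

# Duplex initiation terms per terminal base pair.
.nnInit <- list("G" = c(dH = 0.1, dS = -2.8), "C" = c(dH = 0.1, dS = -2.8),
                "A" = c(dH = 2.3, dS = 4.1),  "T" = c(dH = 2.3, dS = 4.1))

# Symmetry correction for self-complementary duplexes.
.nnSym <- c(dH = 0, dS = -1.4)

.gasConstant <- 1.98720425864083e-3  # kcal / (mol K)

.checkSequence <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a single non-empty string", call. = FALSE)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq))
    stop(what, " contains characters outside the ACGT alphabet",
         call. = FALSE)
  seq
}

#' Reverse complement of a plain DNA string
#'
#' Extends the \pkg{Biostrings} generic to plain character vectors over the
#' ACGT alphabet, returning the reverse complement 5'->3' as a character
#' string.  Applying it twice returns the input.
#'
#' @param x a single character string over ACGT.
#' @return a character string, the reverse complement of `x`.
#' @examples
#' reverseComplement("GTAGAAGTAGG")  # the complementary linker
#' @export
setMethod("reverseComplement", "character", function(x, ...) {
  x <- .checkSequence(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
})

.nnStack <- function(dinuc) {
  i <- match(dinuc, .nnTable$stack)
  if (is.na(i)) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(dinuc)))
    i <- match(rc, .nnTable$stack)
  }
  c(dH = .nnTable$dH[i], dS = .nnTable$dS[i])
}

#' Hybridization free energy of a perfectly complementary DNA duplex
#'
#' Nearest-neighbor enthalpy and entropy summation (unified SantaLucia
#' parameters) with duplex-initiation terms, the symmetry correction for
#' self-complementary strands, an entropy-based monovalent-salt correction
#' `dS(salt) = dS(1M) + 0.368 * (length - 1) * ln[Na+]`, and an optional
#' constant inert-tail correction.  Only perfect Watson-Crick duplexes are
#' supported: `seqB` must be the reverse complement of `seqA`.
#'
#' @param seqA,seqB 5'->3' sequences of the two strands (ACGT only).
#' @param temperature temperature in Kelvin.
#' @param saltM monovalent salt concentration in mol/L.
#' @param tailPenalty additive correction to the hybridization free energy
#'   in units of k_BT, modelling the effect of the inert double-stranded
#'   tail the sticky end is mounted on (default 0; a constant offset is
#'   absorbed by the strand-number calibration downstream).
#' @return a \linkS4class{DuplexThermo} object.
#' @examples
#' duplexDG0("GTAGAAGTAGG", "CCTACTTCTAC",
#'           temperature = 297.15, saltM = 0.2)
#' @export
duplexDG0 <- function(seqA, seqB, temperature = 297.15, saltM = 0.2,
                      tailPenalty = 0) {
  seqA <- .checkSequence(seqA, "seqA")
  seqB <- .checkSequence(seqB, "seqB")
  if (temperature <= 0) stop("temperature must be positive (Kelvin)")
  if (saltM <= 0) stop("saltM must be positive")
  if (nchar(seqA) < 2)
    stop("duplex must be at least 2 nt long for nearest-neighbor stacks")
  if (seqB != reverseComplement(seqA))
    stop("unsupported duplex: seqB is not the reverse complement of seqA")
  bases <- strsplit(seqA, "")[[1]]
  nStacks <- length(bases) - 1L
  dH <- 0; dS <- 0
  for (i in seq_len(nStacks)) {
    st <- .nnStack(paste0(bases[i], bases[i + 1L]))
    dH <- dH + st[["dH"]]; dS <- dS + st[["dS"]]
  }
  for (end in c(bases[1L], bases[length(bases)])) {
    dH <- dH + .nnInit[[end]][["dH"]]
    dS <- dS + .nnInit[[end]][["dS"]]
  }
  if (seqA == seqB) { dH <- dH + .nnSym[["dH"]]; dS <- dS + .nnSym[["dS"]] }
  dS <- dS + 0.368 * nStacks * log(saltM)
  RT <- .gasConstant * temperature
  dG0 <- dH - temperature * dS / 1000 + tailPenalty * RT
  new("DuplexThermo", seqA = seqA, seqB = seqB, dH = dH, dS = dS,
      temperature = temperature, saltM = saltM, tailPenalty = tailPenalty,
      dG0 = dG0, betaDG0 = dG0 / RT)
}

#' Read a linker sequence from a FASTA file
#'
#' Reads a single-record FASTA file and returns the sequence as a plain
#' string (the description is ignored).
#'
#' @param path path to a FASTA file with exactly one record.
#' @return a character string.
#' @export
readLinkerFasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L)
    stop("expected exactly one FASTA record, found ", length(set))
  .checkSequence(as.character(set[[1L]]))
}

#' Tabulate duplex thermodynamics
#'
#' Collects one or more \linkS4class{DuplexThermo} objects into a
#' data.frame suitable for CSV export.
#'
#' @param ... DuplexThermo objects.
#' @return a data.frame with one row per duplex.
#' @export
thermoTable <- function(...) {
  xs <- list(...)
  do.call(rbind, lapply(xs, function(d) {
    data.frame(seqA = d@seqA, seqB = d@seqB,
               temperature_K = d@temperature, salt_M = d@saltM,
               dH_kcal = d@dH, dS_cal = d@dS, dG0_kcal = d@dG0,
               beta_dG0 = d@betaDG0, stringsAsFactors = FALSE)
  }))
}
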