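# Peptide sequences, single-amino-acid-polymorphism (SAP) variants and
# mass / m-over-z arithmetic for epitope peptides and intact antibodies.

# Monoisotopic residue masses (Da), canonical 20 amino acids.
.aa_mono <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Average residue masses (Da).
.aa_avg <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

#' Residue and adduct mass table
#'
#' Monoisotopic and average residue masses (Da) for the 20 canonical amino
#' acids together with the terminal water, proton and sodium-adduct mass
#' shifts used throughout the package.
#'
#' @return A list with components `monoisotopic`, `average` (named numeric
#'   vectors, residue -> Da), `water_mono`, `water_avg`, `proton`
#'   and `sodium_adduct` (Da).
#' @examples
#' mass_table()$proton
#' @export
mass_table <- function() {
  list(
    monoisotopic = .aa_mono,
    average = .aa_avg,
    water_mono = 18.010565,
    water_avg = 18.01528,
    proton = 1.007276,
    sodium_adduct = 21.981943
  )
}

.proton <- 1.007276
.water_mono <- 18.010565
.water_avg <- 18.01528
.na_adduct <- 21.981943

.check_sequence <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  bad <- which(!aa %in% names(.aa_mono))
  if (length(bad) > 0L) {
    stop(sprintf("non-canonical residue '%s' at position %d", aa[bad[1]], bad[1]),
         call. = FALSE)
  }
  aa
}

#' Construct an epitope peptide variant
#'
#' A peptide variant anchors a one-letter amino acid sequence at a residue
#' number of the parent antigen (the studied epitope covers residues
#' 184-198 of human cardiac troponin I) and records any single amino acid
#' polymorphism (SAP) edits applied relative to the wild type.
#'
#' @param sequence One-letter amino acid string (canonical residues only).
#' @param start_residue Residue number of the first position (default 184).
#' @param saps List of applied edits, each a list with `from`, `pos`, `to`.
#' @param label Free-text label (e.g. `"R192Q"`).
#' @return An object of class `peptide_variant`.
#' @examples
#' wt <- peptide_variant("ENREVGDWRKNIDAL", 184, label = "wt")
#' @export
peptide_variant <- function(sequence, start_residue = 184L, saps = list(),
                            label = "wt") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("sequence must be non-empty", call. = FALSE)
  sequence <- toupper(sequence)
  .check_sequence(sequence)
  start_residue <- as.integer(start_residue)
  for (s in saps) {
    if (s$pos < start_residue || s$pos > start_residue + nchar(sequence) - 1L) {
      stop(sprintf("SAP position %d outside residue range [%d, %d]",
                   s$pos, start_residue, start_residue + nchar(sequence) - 1L),
           call. = FALSE)
    }
  }
  structure(
    list(sequence = sequence, start_residue = start_residue,
         saps = saps, label = label),
    class = "peptide_variant"
  )
}

#' @export
print.peptide_variant <- function(x, ...) {
  edits <- vapply(x$saps, function(s) sprintf("%s%d%s", s$from, s$pos, s$to), "")
  cat(sprintf("peptide_variant %s: %s (aa%d-aa%d)%s\n",
              x$label, x$sequence, x$start_residue,
              x$start_residue + nchar(x$sequence) - 1L,
              if (length(edits)) paste0(" [", paste(edits, collapse = "+"), "]")
              else ""))
  invisible(x)
}

.parse_edit <- function(edit) {
  m <- regmatches(edit, regexec("^([A-Z])([0-9]+)([A-Z])$", edit))[[1]]
  if (length(m) != 4L) {
    stop(sprintf("cannot parse SAP edit '%s' (expected e.g. \"R192Q\")", edit),
         call. = FALSE)
  }
  list(from = m[2], pos = as.integer(m[3]), to = m[4])
}

#' Apply single amino acid polymorphism edits to a peptide
#'
#' Applies one or more edits in `X<n>Y` notation (original residue, residue
#' number on the parent protein, replacement residue) to a wild-type
#' peptide. Chained edits (e.g. `c("R192P", "K193E")`) are applied in order.
#'
#' @param wildtype A [peptide_variant()].
#' @param edits Character vector of edits such as `"R186Q"`.
#' @param label Label for the resulting variant; defaults to the edits
#'   joined with `+`.
#' @return A new `peptide_variant` with the edits applied and recorded.
#' @examples
#' wt <- peptide_variant("ENREVGDWRKNIDAL", 184)
#' apply_sap(wt, "R186Q")$sequence   # "ENQEVGDWRKNIDAL"
#' @export
apply_sap <- function(wildtype, edits, label = NULL) {
  stopifnot(inherits(wildtype, "peptide_variant"))
  aa <- strsplit(wildtype$sequence, "")[[1]]
  saps <- wildtype$saps
  for (edit in edits) {
    e <- .parse_edit(edit)
    i <- e$pos - wildtype$start_residue + 1L
    if (i < 1L || i > length(aa)) {
      stop(sprintf("edit %s: residue %d outside peptide range", edit, e$pos),
           call. = FALSE)
    }
    if (aa[i] != e$from) {
      stop(sprintf("edit %s: expected %s at residue %d but found %s",
                   edit, e$from, e$pos, aa[i]), call. = FALSE)
    }
    aa[i] <- e$to
    saps <- c(saps, list(e))
  }
  peptide_variant(paste(aa, collapse = ""), wildtype$start_residue,
                  saps = saps,
                  label = if (is.null(label)) paste(edits, collapse = "+")
                          else label)
}

.sequence_of <- function(p) {
  if (inherits(p, "peptide_variant")) p$sequence else toupper(as.character(p))
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water (18.010565 Da).
#'
#' @param p A `peptide_variant` or a character sequence.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("ENREVGDWRKNIDAL")  # 1813.907
#' @export
monoisotopic_mass <- function(p) {
  s <- .sequence_of(p)
  if (nchar(s) == 0L) stop("sequence must be non-empty", call. = FALSE)
  aa <- .check_sequence(s)
  sum(.aa_mono[aa]) + .water_mono
}

#' Average peptide mass
#'
#' Sum of residue average masses plus one water (18.01528 Da).
#'
#' @inheritParams monoisotopic_mass
#' @return Mass in Da.
#' @export
average_mass <- function(p) {
  s <- .sequence_of(p)
  if (nchar(s) == 0L) stop("sequence must be non-empty", call. = FALSE)
  aa <- .check_sequence(s)
  sum(.aa_avg[aa]) + .water_avg
}

#' Mass-to-charge ratio of a protonated ion
#'
#' `(mass + z * 1.007276) / z` for the `[M + zH]^z+` ion.
#'
#' @param mass Neutral mass in Da (vectorised).
#' @param z Positive integer charge (vectorised).
#' @return m/z in Thomson.
#' @examples
#' mz(1813.907, 3)  # 605.64
#' @export
mz <- function(mass, z) {
  if (any(z < 1) || any(z != round(z))) {
    stop("charge z must be a positive integer", call. = FALSE)
  }
  (mass + z * .proton) / z
}

#' Epitope peptide panel of the troponin I study system
#'
#' Builds the eight-variant panel covering residues 184-198 of human cardiac
#' troponin I: the wild type plus seven SAP variants at residues 186, 190,
#' 192 and 193 (the double variant carries R192P and K193E).
#'
#' @return Named list of [peptide_variant()] objects (`"1"` .. `"8"`).
#' @examples
#' panel <- troponin_epitope_panel()
#' panel[["2"]]$sequence
#' @export
troponin_epitope_panel <- function() {
  wt <- peptide_variant("ENREVGDWRKNIDAL", 184L, label = "wt")
  edits <- list(NULL, "R186Q", "R192H", "R192L", "R192C", "D190G", "R192P",
                c("R192P", "K193E"))
  out <- lapply(edits, function(e) if (is.null(e)) wt else apply_sap(wt, e))
  names(out) <- as.character(seq_along(out))
  out
}

#' Peptide mass report
#'
#' Tabulates label, sequence, applied edits, monoisotopic mass and the
#' calculated m/z at the requested charge for each peptide.
#'
#' @param peptides List of `peptide_variant` objects.
#' @param charges Integer vector of charges, recycled across peptides.
#' @return A data.frame with columns `label`, `sequence`, `saps`,
#'   `mono_mass` (3 dp), `charge`, `calc_mz` (2 dp).
#' @export
mass_report <- function(peptides, charges = 3L) {
  charges <- rep_len(as.integer(charges), length(peptides))
  rows <- mapply(function(p, z) {
    m <- monoisotopic_mass(p)
    data.frame(
      label = p$label, sequence = p$sequence,
      saps = paste(vapply(p$saps, function(s) sprintf("%s%d%s", s$from, s$pos, s$to), ""),
                   collapse = "+"),
      mono_mass = round(m, 3), charge = z, calc_mz = round(mz(m, z), 2),
      stringsAsFactors = FALSE
    )
  }, peptides, charges, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}

#' Read peptide definitions from CSV
#'
#' Expects columns `label`, `sequence`, `start` and optionally `saps`
#' (edits joined with `+`, applied for record-keeping validation against
#' the stored sequence when a wild-type row labelled `wt` is present).
#'
#' @param path CSV file path.
#' @return Named list of `peptide_variant` objects.
#' @export
read_peptides_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "sequence", "start") %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(i) {
    saps <- list()
    if ("saps" %in% names(df) && !is.na(df$saps[i]) && nzchar(df$saps[i])) {
      saps <- lapply(strsplit(df$saps[i], "+", fixed = TRUE)[[1]], .parse_edit)
    }
    peptide_variant(df$sequence[i], df$start[i], saps = saps,
                    label = df$label[i])
  })
  names(out) <- df$label
  out
}

#' Read peptide definitions from FASTA
#'
#' Headers carry the label and anchor residue as `label|start=184`.
#' Requires the Biostrings package.
#'
#' @param path FASTA file path.
#' @return Named list of `peptide_variant` objects.
#' @export
read_peptides_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package", call. = FALSE)
  }
  seqs <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    header <- names(seqs)[i]
    parts <- strsplit(header, "|", fixed = TRUE)[[1]]
    label <- parts[1]
    start <- 1L
    for (p in parts[-1]) {
      kv <- strsplit(p, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2L && kv[1] == "start") start <- as.integer(kv[2])
    }
    peptide_variant(as.character(seqs[[i]]), start, label = label)
  })
  names(out) <- vapply(out, function(p) p$label, "")
  out
}
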