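## ---------------------------------------------------------------------------
## glycoid: in-silico digestion, glycopeptide enumeration, mass assignment
## ---------------------------------------------------------------------------

## monoisotopic residue masses (Da); Cys is carried unmodified here and the
## carbamidomethyl fixed modification (+57.02146, iodoacetamide alkylation)
## is added per Cys in peptide_mass()
.residue_mass <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

.mass_water <- 18.01056
.mass_cam <- 57.02146        # carbamidomethyl on Cys
.mass_proton <- 1.007276

## monosaccharide residue masses (Da)
.glycan_mass <- c(Hex = 162.05282, HexNAc = 203.07937,
                  NeuAc = 291.09542, Fuc = 146.05791)

#' Monoisotopic peptide mass
#'
#' Sum of residue masses plus one water, with carbamidomethyl (+57.02146)
#' on every cysteine (fixed alkylation).
#'
#' @param peptide amino-acid string (20-letter alphabet).
#' @return neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(peptide) {
  vapply(peptide, function(p) {
    aa <- strsplit(p, "", fixed = TRUE)[[1]]
    bad <- setdiff(aa, names(.residue_mass))
    if (length(bad))
      stop_config("illegal residue(s) in peptide: %s",
                  paste(unique(bad), collapse = ", "))
    sum(.residue_mass[aa]) + .mass_water + sum(aa == "C") * .mass_cam
  }, numeric(1), USE.NAMES = FALSE)
}

## positions of N-X-S/T sequons (X != P) fully inside `seq`, 1-based
sequon_positions <- function(seq) {
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(aa)
  if (n < 3L) return(integer(0))
  i <- seq_len(n - 2L)
  i[aa[i] == "N" & aa[i + 1L] != "P" & aa[i + 2L] %in% c("S", "T")]
}

#' In-silico tryptic/Lys-C digestion with sequon filtering
#'
#' Cleaves C-terminal to K or R except before P, allows up to `max_missed`
#' missed cleavages, and keeps only peptides containing at least one
#' N-glycosylation sequon N-X-S/T (X != P) fully within the peptide. One
#' row is returned per (peptide occurrence, sequon site).
#'
#' @param protein_sequence amino-acid string (or named character vector of
#'   proteins; names become `protein_id`).
#' @param max_missed maximum missed cleavages (default 2).
#' @param protein_id id used when `protein_sequence` is unnamed.
#' @return data.frame: protein_id, peptide, start, end (1-based protein
#'   coordinates), n_missed, site (protein position of the sequon Asn),
#'   site_in_peptide, peptide_mass.
#' @export
digest <- function(protein_sequence, max_missed = 2, protein_id = "protein1") {
  if (length(protein_sequence) > 1L) {
    ids <- names(protein_sequence) %||%
      sprintf("protein%d", seq_along(protein_sequence))
    return(do.call(rbind, Map(function(s, id)
      digest(s, max_missed = max_missed, protein_id = id),
      protein_sequence, ids)))
  }
  if (!is.null(names(protein_sequence)))
    protein_id <- names(protein_sequence)
  seq <- toupper(protein_sequence)
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(aa, names(.residue_mass))
  if (length(bad))
    stop_config("illegal residue(s) in sequence: %s",
                paste(unique(bad), collapse = ", "))
  n <- length(aa)
  empty <- data.frame(protein_id = character(0), peptide = character(0),
                      start = integer(0), end = integer(0),
                      n_missed = integer(0), site = integer(0),
                      site_in_peptide = integer(0),
                      peptide_mass = numeric(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  ## cleavage boundaries: after position i when aa[i] in {K,R} and
  ## aa[i+1] != P; `bounds` are fragment end positions
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- unique(c(cut_after, n))
  starts <- c(1L, head(bounds, -1L) + 1L)
  nfrag <- length(bounds)

  rows <- list()
  for (i in seq_len(nfrag)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nfrag) break
      s <- starts[i]; e <- bounds[j]
      pep <- substr(seq, s, e)
      sites <- sequon_positions(pep)
      if (!length(sites)) next
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = protein_id, peptide = pep,
        start = s, end = e, n_missed = m,
        site = s + sites - 1L, site_in_peptide = sites,
        peptide_mass = peptide_mass(pep), stringsAsFactors = FALSE,
        row.names = NULL)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default glycan composition grid
#'
#' Hex 3-9, HexNAc 2-6, NeuAc 0-4, Fuc 0-2: bi- to tetra-antennary
#' N-glycans including the fully sialylated biantennary composition
#' Hex5HexNAc4NeuAc2.
#'
#' @return named list of integer ranges.
#' @export
default_glycan_ranges <- function() {
  list(Hex = 3:9, HexNAc = 2:6, NeuAc = 0:4, Fuc = 0:2)
}

#' Enumerate theoretical glycopeptide candidates
#'
#' Cartesian product of sequon-bearing peptides and the glycan composition
#' grid. Neutral mass is the peptide monoisotopic mass (water and fixed
#' modifications included) plus the composition mass: Hex 162.05282,
#' HexNAc 203.07937, NeuAc 291.09542, Fuc 146.05791 Da per residue.
#'
#' @param peptides data.frame from [digest()] (needs peptide, site,
#'   peptide_mass, protein_id columns).
#' @param glycan_ranges named list of integer vectors for Hex, HexNAc,
#'   NeuAc, Fuc (see [default_glycan_ranges()]).
#' @return data.frame of candidates: protein_id, peptide, site, Hex,
#'   HexNAc, NeuAc, Fuc, neutral_mass.
#' @export
enumerate_candidates <- function(peptides,
                                 glycan_ranges = default_glycan_ranges()) {
  need <- c("Hex", "HexNAc", "NeuAc", "Fuc")
  if (!all(need %in% names(glycan_ranges)))
    stop_config("glycan_ranges must name: %s", paste(need, collapse = ", "))
  grid <- expand.grid(Hex = glycan_ranges$Hex, HexNAc = glycan_ranges$HexNAc,
                      NeuAc = glycan_ranges$NeuAc, Fuc = glycan_ranges$Fuc,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(peptides) == 0L || nrow(grid) == 0L)
    return(data.frame(protein_id = character(0), peptide = character(0),
                      site = integer(0), Hex = integer(0),
                      HexNAc = integer(0), NeuAc = integer(0),
                      Fuc = integer(0), neutral_mass = numeric(0)))
  gmass <- as.matrix(grid) %*% .glycan_mass[need]
  ip <- rep(seq_len(nrow(peptides)), each = nrow(grid))
  ig <- rep(seq_len(nrow(grid)), times = nrow(peptides))
  out <- data.frame(protein_id = peptides$protein_id[ip],
                    peptide = peptides$peptide[ip],
                    site = peptides$site[ip],
                    grid[ig, , drop = FALSE],
                    neutral_mass = peptides$peptide_mass[ip] + gmass[ig],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Match observed features to glycopeptide candidates by neutral mass
#'
#' Negative ion mode: a feature observed at m/z as `[M - zH]^z-` has
#' observed neutral mass `z * mz + z * 1.007276`. Every (feature,
#' candidate, charge) pair whose mass difference is within `tol`
#' (inclusive) is reported, sorted by |delta|; no unique assignment is
#' forced.
#'
#' @param features a [feature_matrix] or data.frame with `feature_id` and
#'   `mz` columns.
#' @param candidates data.frame from [enumerate_candidates()].
#' @param charges integer charges considered (default 1:4).
#' @param tol mass tolerance in Da (default 0.03).
#' @return data.frame of assignments: feature_id, candidate_row,
#'   protein_id, peptide, site, Hex, HexNAc, NeuAc, Fuc, charge,
#'   observed_neutral, delta_mass (observed - theoretical).
#' @export
match_features <- function(features, candidates, charges = 1:4, tol = 0.03) {
  if (tol <= 0) stop_config("mass tolerance must be > 0")
  if (inherits(features, "feature_matrix")) features <- features$features
  stopifnot(all(c("feature_id", "mz") %in% names(features)))
  o <- order(candidates$neutral_mass)
  cm <- candidates$neutral_mass[o]
  hits <- list()
  for (z in charges) {
    obs <- z * features$mz + z * .mass_proton
    lo <- findInterval(obs - tol, cm) + 1L
    hi <- findInterval(obs + tol, cm)
    any_hit <- which(hi >= lo)
    for (f in any_hit) {
      idx <- o[lo[f]:hi[f]]
      hits[[length(hits) + 1L]] <- data.frame(
        feature_id = features$feature_id[f], candidate_row = idx,
        charge = z, observed_neutral = obs[f],
        delta_mass = obs[f] - candidates$neutral_mass[idx],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(feature_id = character(0), candidate_row = integer(0),
                      protein_id = character(0), peptide = character(0),
                      site = integer(0), Hex = integer(0), HexNAc = integer(0),
                      NeuAc = integer(0), Fuc = integer(0), charge = integer(0),
                      observed_neutral = numeric(0), delta_mass = numeric(0)))
  a <- do.call(rbind, hits)
  a <- a[abs(a$delta_mass) <= tol, , drop = FALSE]   # inclusive boundary
  a <- a[order(abs(a$delta_mass)), , drop = FALSE]
  cand_cols <- candidates[a$candidate_row,
                          c("protein_id", "peptide", "site",
                            "Hex", "HexNAc", "NeuAc", "Fuc"),
                          drop = FALSE]
  out <- cbind(a[, c("feature_id", "candidate_row"), drop = FALSE],
               cand_cols,
               a[, c("charge", "observed_neutral", "delta_mass"),
                 drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Normalize EGP levels to a transferrin feature
#'
#' Divides every feature's level by the sample's transferrin level,
#' removing per-sample global scale (sample-preparation variability).
#' Samples with a zero transferrin level cannot be normalized; they are
#' dropped and listed in `attr(, "flagged_samples")`.
#'
#' @param egp_matrix a [feature_matrix] of relative levels.
#' @param transferrin_feature_id id of the transferrin anchor feature.
#' @return a [feature_matrix] of transferrin-normalized levels.
#' @export
normalize_to_transferrin <- function(egp_matrix, transferrin_feature_id) {
  idx <- match(transferrin_feature_id, egp_matrix$features$feature_id)
  if (is.na(idx))
    stop_config("transferrin feature '%s' not present", transferrin_feature_id)
  tf <- egp_matrix$values[idx, ]
  flagged <- colnames(egp_matrix$values)[tf <= 0]
  keep <- tf > 0
  vals <- sweep(egp_matrix$values[, keep, drop = FALSE], 2L, tf[keep], "/")
  out <- feature_matrix(egp_matrix$features, vals,
                        provenance = egp_matrix$provenance)
  attr(out, "flagged_samples") <- flagged
  out
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over Biostrings.
#'
#' @param path FASTA file path.
#' @return named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop_config("read_fasta requires the Biostrings package")
  s <- Biostrings::readAAStringSet(path)
  setNames(as.character(s), sub("\\s.*$", "", names(s)))
}
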