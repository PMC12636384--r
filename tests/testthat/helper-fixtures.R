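## shared fixture builders; everything is generated in code at test time

small_config <- function(...) {
  defaults <- list(
    n_per_group = c(healthy = 30, CRC = 10, GC = 6, EC = 4),
    n_true_egps = 150, frac_differential = 0.2, n_signature = 2,
    n_noise_per_sample = 40, seed = 101L)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

## clean simulation: no satellites, no noise peaks, no dropout
clean_config <- function(...) {
  small_config(satellite_rates = c(isotope = 0, adduct = 0, fragment = 0),
               n_noise_per_sample = 0, lod = 0, ...)
}

## empirical AUC of a score against binary labels (package-independent path
## is exercised elsewhere; this is just a convenience on roc_auc)
emp_auc <- function(score, y) roc_auc(score, y)$auc

## independent residue-summation oracle with its own constants, used to
## check peptide and candidate masses computed by the package
oracle_mass <- local({
  aa <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
          V = 99.06841, T = 101.04768, C = 103.00919 + 57.02146,
          L = 113.08406, I = 113.08406, N = 114.04293, D = 115.02694,
          Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
          H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333,
          W = 186.07931)
  sugars <- c(Hex = 162.05282, HexNAc = 203.07937, NeuAc = 291.09542,
              Fuc = 146.05791)
  function(pep, hex = 0, hexnac = 0, neuac = 0, fuc = 0) {
    r <- strsplit(pep, "")[[1]]
    sum(aa[r]) + 18.01056 +
      sum(c(hex, hexnac, neuac, fuc) * sugars)
  }
})

## map recovered features onto the planted species registry by coordinates
match_registry <- function(features, registry, tol_mz = 0.06, tol_rt = 0.3) {
  vapply(seq_len(nrow(registry)), function(i) {
    j <- which(abs(features$mz - registry$mz[i]) <= tol_mz &
                 abs(features$rt - registry$rt[i]) <= tol_rt)
    if (length(j)) j[which.min(abs(features$mz[j] - registry$mz[i]))]
    else NA_integer_
  }, integer(1))
}
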