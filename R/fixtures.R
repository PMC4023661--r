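# Deterministic demonstration-data generators. All randomness goes through
# R's Mersenne-Twister with inversion normals under an explicit seed, with the
# caller's RNG state restored afterwards, so the same seed reproduces the same
# matrix on every platform.

#' The 20 standard amino acids, one-letter codes, alphabetical
#' @format Character vector of length 20.
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

#' Enumerate the non-native substitutions of a residue
#'
#' For a wildtype residue, the 19 possible single amino-acid substitutions:
#' the standard 20-letter alphabet minus the wildtype, in alphabetical order.
#'
#' @param wildtype a single one-letter amino-acid code.
#' @return Character vector of length 19.
#' @examples
#' length(enumerate_substitutions("A")) # 19
#' @export
enumerate_substitutions <- function(wildtype) {
  if (!is.character(wildtype) || length(wildtype) != 1L ||
      !wildtype %in% AMINO_ACIDS)
    hm_abort("BAD_RESIDUE",
             sprintf("'%s' is not a standard one-letter amino-acid code",
                     as.character(wildtype)[1]))
  setdiff(AMINO_ACIDS, wildtype)
}

#' Default trans-membrane-like high-effect regions
#'
#' Seven evenly spaced helical segments spanning roughly the central 16-88%
#' of the sequence, echoing the seven-trans-membrane architecture of rhodopsin
#' (TM region residues 55-306 of 348).
#'
#' @param L sequence length.
#' @param n_regions number of segments.
#' @return List of `c(start, end)` 1-based inclusive integer intervals.
#' @export
default_tm_regions <- function(L, n_regions = 7L) {
  if (L < 3L) return(list())
  centers <- round(seq(0.16 * L, 0.88 * L, length.out = n_regions))
  half <- max(1L, round(0.045 * L))
  out <- lapply(centers, function(cen)
    c(max(1L, cen - half), min(L, cen + half)))
  Filter(function(iv) iv[1] <= iv[2], out)
}

#' Specification for a synthetic mutability landscape
#'
#' @param sequence amino-acid string over the 20 standard residues (the
#'   wildtype protein).
#' @param high_effect_regions list of `c(start, end)` 1-based inclusive
#'   residue intervals where substitutions have strong predicted effects
#'   (e.g. trans-membrane helices); defaults to [default_tm_regions()].
#' @param baseline_mean mean effect score outside the regions (low effect).
#' @param region_mean mean effect score inside (must exceed `baseline_mean`).
#' @param noise_sd standard deviation of the per-cell Gaussian noise.
#' @param seed RNG seed.
#' @return A `mutability_spec` object.
#' @export
mutability_spec <- function(sequence,
                            high_effect_regions = default_tm_regions(nchar(sequence)),
                            baseline_mean = -1.5, region_mean = 1.5,
                            noise_sd = 0.75, seed = 1L) {
  res <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(res, AMINO_ACIDS)
  if (length(bad))
    hm_abort("BAD_RESIDUE",
             sprintf("sequence contains non-standard residue(s): %s",
                     paste(unique(bad), collapse = ", ")))
  L <- length(res)
  for (iv in high_effect_regions)
    if (iv[1] < 1 || iv[2] > L || iv[1] > iv[2])
      hm_abort("RANGE_ERROR",
               sprintf("region [%d, %d] outside sequence of length %d",
                       iv[1], iv[2], L))
  if (region_mean <= baseline_mean)
    hm_abort("RANGE_ERROR", "region_mean must exceed baseline_mean")
  structure(list(sequence = res, high_effect_regions = high_effect_regions,
                 baseline_mean = baseline_mean, region_mean = region_mean,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "mutability_spec")
}

#' Generate a synthetic protein mutability landscape
#'
#' Emulates the structure of a predicted mutability landscape: a 20-row
#' (amino acids, alphabetical) by L-column (positions, labeled
#' `"<residue><position>"`) matrix of substitution effect scores. The cell
#' where the substituted residue equals the native one is flagged `WILDTYPE`
#' (rendered black, no score); every other cell draws from
#' `Normal(region_mean, noise_sd)` inside a high-effect region and
#' `Normal(baseline_mean, noise_sd)` elsewhere. A secondary-structure track
#' marks the regions as helices (`"H"`, red). The scores are synthetic — this
#' emulates only the visual structure of a landscape, not any effect
#' predictor.
#'
#' @param spec a [mutability_spec()].
#' @return List with elements `matrix` (a [heat_matrix()]) and `track`.
#' @examples
#' fx <- gen_mutability_fixture(mutability_spec("ACDEFGHIKL", seed = 7))
#' dim(fx$matrix)        # 20 x 10
#' sum(fx$matrix$flags == "WILDTYPE") # one per column
#' @export
gen_mutability_fixture <- function(spec) {
  stopifnot(inherits(spec, "mutability_spec"))
  L <- length(spec$sequence)
  in_region <- rep(FALSE, L)
  for (iv in spec$high_effect_regions)
    in_region[iv[1]:iv[2]] <- TRUE
  values <- with_seed(spec$seed, {
    mu <- matrix(rep(ifelse(in_region, spec$region_mean, spec$baseline_mean),
                     each = 20L), 20L, L)
    mu + matrix(stats::rnorm(20L * L, 0, spec$noise_sd), 20L, L)
  })
  flags <- matrix("NONE", 20L, L)
  for (pos in seq_len(L)) {
    i <- match(spec$sequence[pos], AMINO_ACIDS)
    flags[i, pos] <- "WILDTYPE"
    values[i, pos] <- 0   # wildtype carries no effect score; drawn black
  }
  m <- heat_matrix(values, AMINO_ACIDS,
                   paste0(spec$sequence, seq_len(L)), flags)
  tr <- track("SecStr", ifelse(in_region, "H", NA_character_),
              c(H = "#ff0000", E = "#0000ff"))
  list(matrix = m, track = tr)
}

#' Generate a synthetic probe-level expression matrix
#'
#' Emulates a probe-by-condition microarray view of a single gene: log2
#' expression values for `n_probes` probes (columns) under `n_conditions`
#' experimental conditions (rows; `"control"` and `"case"` when there are
#' two), with two annotation tracks locating each probe on the gene's exons
#' (round-robin over `n_exons`) and on trans-membrane regions (`n_tm` regions,
#' with some probes unassigned). Per-probe baselines are drawn once, and a
#' subset of probes receives a condition-dependent differential-expression
#' shift, so probe colors differ between rows.
#'
#' @param n_probes number of probes (columns), default 8.
#' @param n_conditions number of conditions (rows), default 2.
#' @param seed RNG seed.
#' @param n_exons number of exon categories, default 5.
#' @param n_tm number of trans-membrane categories, default 7.
#' @return List with elements `matrix` (a [heat_matrix()]) and `tracks`
#'   (exon track, TM track).
#' @export
gen_expression_fixture <- function(n_probes = 8L, n_conditions = 2L,
                                   seed = 1L, n_exons = 5L, n_tm = 7L) {
  stopifnot(n_probes >= 1, n_conditions >= 1)
  vals <- with_seed(seed, {
    baseline <- stats::runif(n_probes, 5, 10)       # per-probe log2 level
    de <- stats::rnorm(n_probes, 0, 1.2)            # differential shift
    de[stats::runif(n_probes) < 0.4] <- 0           # not all probes respond
    shift <- outer(seq_len(n_conditions) - 1L, de)  # grows along conditions
    sweep(shift, 2L, baseline, `+`) +
      matrix(stats::rnorm(n_conditions * n_probes, 0, 0.3),
             n_conditions, n_probes)
  })
  row_labels <- if (n_conditions == 2L) c("control", "case")
                else paste0("condition", seq_len(n_conditions))
  col_labels <- paste0("probe", seq_len(n_probes))
  m <- heat_matrix(vals, row_labels, col_labels)

  exon_cats <- paste0("E", rep_len(seq_len(n_exons), n_probes))
  exon_pal <- stats::setNames(
    grDevices::hcl(seq(15, 375, length.out = n_exons + 1L)[seq_len(n_exons)],
                   60, 70),
    paste0("E", seq_len(n_exons)))
  exon_track <- track("Exon", exon_cats, tolower(exon_pal))

  tm_cats <- rep(NA_character_, n_probes)
  assigned <- which(seq_len(n_probes) %% 4L != 0L)  # every 4th probe is
  tm_cats[assigned] <-                              # outside any TM region
    paste0("TM", ((seq_along(assigned) - 1L) %% n_tm) + 1L)
  tm_pal <- stats::setNames(
    grDevices::gray(seq(0.25, 0.8, length.out = n_tm)),
    paste0("TM", seq_len(n_tm)))
  tm_track <- track("TM", tm_cats, tolower(tm_pal))

  list(matrix = m, tracks = list(exon_track, tm_track))
}

#' Deterministic pseudo-protein sequence
#'
#' A seeded random sequence over the 20 standard residues, used by the
#' mutability demo when the caller supplies no protein.
#'
#' @param L sequence length.
#' @param seed RNG seed.
#' @return A single string of length `L`.
#' @export
random_protein <- function(L, seed = 1L) {
  with_seed(seed, paste(sample(AMINO_ACIDS, L, replace = TRUE), collapse = ""))
}
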