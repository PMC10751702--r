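#' @importFrom Rcpp evalCpp
#' @importFrom data.table data.table rbindlist setorder := .N setnames copy as.data.table fwrite fread
#' @importFrom stats approx runif rexp setNames sd
#' @importFrom utils head tail
#' @useDynLib dnatrackmc, .registration = TRUE
NULL

# package-local memo store (default cross-section library, etc.)
.pkg_env <- new.env(parent = emptyenv())

#' Pinned physical constants and element tables
#'
#' All coordinates in the package are nanometres, energies are electronvolts,
#' masses are Daltons.  The van der Waals radii and standard atomic masses are
#' a single editable constant set used everywhere.
#'
#' @format Named numeric vectors keyed by element symbol.
#' @name physics-constants
NULL

#' @rdname physics-constants
#' @export
VDW_RADII_NM <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, P = 0.180)

#' @rdname physics-constants
#' @export
ATOMIC_MASS_DA <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974)

# unit conversions (CODATA values)
EV_TO_JOULE <- 1.602176634e-19
DALTON_TO_KG <- 1.66053907e-27
# 1 g/cm^3 expressed in Da/nm^3
G_CM3_TO_DA_NM3 <- 1e-21 / 1.66053907e-24

# molecule vocabulary --------------------------------------------------------

MOLECULE_KINDS <- c("adenine", "cytosine", "guanine", "thymine",
                    "deoxyribose", "phosphate")
BASE_KINDS <- MOLECULE_KINDS[1:4]
BACKBONE_KINDS <- c("deoxyribose", "phosphate")

molecule_group <- function(kind) {
  ifelse(kind %in% BACKBONE_KINDS, "backbone", "base")
}

# interaction channels as they appear in event streams
EVENT_CHANNELS <- c("elastic", "vibrational_excitation",
                    "electronic_excitation", "ionization", "dea")
# channels competing at the sampling stage (vibrational and electronic
# excitation share one cross-section table; the realized level decides which
# of the two the event is recorded as)
SAMPLING_CHANNELS <- c("elastic", "excitation", "ionization", "dea")

BREAK_CHANNELS <- c("dea", "electronic_excitation", "ionization")

# helpers ---------------------------------------------------------------------

# run code under a temporary RNG state derived from `seed`, restoring the
# caller's stream afterwards
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# counter-based seed derivation; keeps results in [1, 2^31 - 2] exactly
# representable in doubles
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) %% 2147483647 + counter * 2654435761) %%
               2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length direction vector")
  v / n
}

# two unit vectors orthogonal to `axis` (and to each other)
orthobasis <- function(axis) {
  axis <- unitize(axis)
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(ref - sum(ref * axis) * axis)
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(e1 = e1, e2 = e2)
}
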