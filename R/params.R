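## Parameter registry: every legal key, with a one-line description used in
## error messages. Vector-valued keys (per phosphorylation state) are marked.

.PARAM_FIELDS <- c(
  ## cyclase (two Ca2+-dependent ROS-GC/GCAP components)
  alpha_min   = "minimum cGMP synthesis rate, high Ca2+ limit (uM/s)",
  alpha_max   = "maximum cGMP synthesis rate, low Ca2+ limit (uM/s)",
  beta        = "weight of the K_cyc1 (GCAP1-like) cyclase component, in [0,1]",
  K_cyc1      = "Ca2+ for half-maximal component-1 cyclase activation (uM)",
  K_cyc2      = "Ca2+ for half-maximal component-2 cyclase activation (uM)",
  m_cyc1      = "Hill exponent of cyclase component 1",
  m_cyc2      = "Hill exponent of cyclase component 2",
  ## hydrolysis
  k_hyd       = "catalytic rate of cGMP hydrolysis by a basal PDE subunit (1/(uM s))",
  k_sigma_hyd = "catalytic rate of cGMP hydrolysis by an activated PDE subunit (1/(uM s))",
  ## CNG channel
  j_cG_max    = "CNG current at saturating cGMP (pA)",
  K_cG_min    = "channel cGMP affinity at low Ca2+ (uM)",
  K_cG_max    = "channel cGMP affinity at high Ca2+ (uM)",
  m_cG        = "Hill exponent of channel opening by cGMP",
  m_CaM       = "Hill exponent of the calmodulin effect on K_cG",
  K_CaM       = "Ca2+ for half-maximal calmodulin effect (uM)",
  f_Ca        = "fraction of CNG current carried by Ca2+",
  ## exchanger
  j_ex_sat    = "saturated Na+/Ca2+,K+ exchange current (pA)",
  K_ex        = "Ca2+ at half-maximal exchange current (uM)",
  ## calcium bookkeeping and geometry
  B_Ca        = "dimensionless cytosolic Ca2+ buffering capacity",
  F_const     = "Faraday constant (C/mol)",
  V_cyt       = "cytosolic outer-segment volume (um^3)",
  ## rhodopsin chain
  n_sites     = "maximum number of phosphorylations (6 for mouse)",
  lambda_max  = "maximal phosphorylation rate per state (1/s; scalar or length n+1, last 0)",
  mu_max      = "arrestin binding rate for states with >= 3 phosphates (1/s)",
  ## recoverin / rhodopsin kinase equilibrium
  K1          = "Ca2+ binding constant of recoverin (uM)",
  K2          = "recoverin membrane-partition constant (uM)",
  K3          = "cytosolic recoverin-RK binding constant (uM)",
  K4          = "membrane recoverin-RK binding constant (uM)",
  M_rec       = "membrane partition weight of recoverin (uM)",
  RK_tot      = "total rhodopsin kinase (uM)",
  Rec_tot     = "total recoverin (uM)",
  ## transducin / PDE / RGS9 front end
  nu_RT       = "transducin activation rate per fully active R* (1/s)",
  nu_per_state = "relative catalytic activity per R* state (length n+1)",
  k_TE        = "rate of T*--E complex formation (1/(uM s))",
  k_f         = "rate of RGS9 binding to T*--E (1/(uM s))",
  k_b         = "rate of RGS9 dissociation from RGS9--T*--E (1/s)",
  k_cat       = "GTP hydrolysis rate of the RGS9--T*--E complex (1/s)",
  T0          = "basal transducin concentration (uM)",
  E0          = "basal PDE catalytic-subunit concentration (uM)",
  RGS9_0      = "basal RGS9 complex concentration (uM)",
  k_E         = "first-order E* shutoff rate of the simplified front end (1/s)",
  ## analytic saturation theory
  nu_RE       = "lumped R* -> E* activation rate (1/s); NA derives it from nu_RT",
  epsilon     = "criterion fraction defining exit from saturation",
  ## geometry
  collecting_area = "effective collecting area converting flash strength to Phi (um^2)"
)

.VECTOR_FIELDS <- c("lambda_max", "nu_per_state")

.PARAMS_SCHEMA <- "pepperberg-params-1"

## Validates a flat value list; returns TRUE or a character vector of messages.
.validateParamValues <- function(v) {
  msgs <- character()
  need <- setdiff(names(.PARAM_FIELDS), names(v))
  if (length(need))
    return(sprintf("missing parameter field(s): %s", paste(need, collapse = ", ")))
  unknown <- setdiff(names(v), names(.PARAM_FIELDS))
  if (length(unknown))
    return(sprintf("unknown parameter field(s): %s", paste(unknown, collapse = ", ")))

  chk <- function(cond, msg) if (!isTRUE(cond)) msgs <<- c(msgs, msg)
  num1 <- function(f) is.numeric(v[[f]]) && length(v[[f]]) == 1 && is.finite(v[[f]])

  for (f in setdiff(names(.PARAM_FIELDS), c(.VECTOR_FIELDS, "nu_RE")))
    chk(num1(f), sprintf("field '%s' must be a single finite number", f))
  chk(is.numeric(v$nu_RE) && length(v$nu_RE) == 1,
      "field 'nu_RE' must be a single number or NA")
  if (length(msgs)) return(msgs)

  n <- v$n_sites
  chk(n >= 1 && n == round(n), "n_sites must be an integer >= 1")

  pos <- c("alpha_min", "alpha_max", "K_cyc1", "K_cyc2", "m_cyc1", "m_cyc2",
           "k_hyd", "k_sigma_hyd", "j_cG_max", "K_cG_min", "K_cG_max", "m_cG",
           "m_CaM", "K_CaM", "f_Ca", "j_ex_sat", "K_ex", "B_Ca", "F_const",
           "V_cyt", "K1", "K2", "K3", "K4", "M_rec", "RK_tot",
           "nu_RT", "k_TE", "k_f", "k_b", "k_cat", "T0", "E0", "RGS9_0",
           "k_E", "epsilon", "collecting_area")
  for (f in pos) chk(v[[f]] > 0, sprintf("field '%s' must be strictly positive", f))
  chk(v$mu_max >= 0, "field 'mu_max' must be non-negative")
  chk(v$Rec_tot >= 0, "field 'Rec_tot' must be non-negative")
  chk(v$beta >= 0 && v$beta <= 1, "field 'beta' must lie in [0,1]")
  chk(v$epsilon < 1, "field 'epsilon' must lie in (0,1)")
  ## equality permitted: it represents the calmodulin-null channel and the
  ## frozen-cyclase (GCAPs knockout) variants respectively
  chk(v$K_cG_min <= v$K_cG_max, "K_cG_min must not exceed K_cG_max")
  chk(v$alpha_min <= v$alpha_max, "alpha_min must not exceed alpha_max")

  lam <- v$lambda_max
  chk(is.numeric(lam) && (length(lam) == 1 || length(lam) == n + 1),
      "lambda_max must be a scalar or a vector of length n+1")
  if (length(lam) == n + 1)
    chk(lam[n + 1] == 0, "lambda_max[n+1] must be 0 (no further phosphorylation)")
  chk(all(lam >= 0), "lambda_max must be non-negative")
  nw <- v$nu_per_state
  chk(is.numeric(nw) && (length(nw) == 1 || length(nw) == n + 1),
      "nu_per_state must be a scalar or a vector of length n+1")
  chk(all(nw >= 0), "nu_per_state must be non-negative")
  if (!is.na(v$nu_RE)) chk(v$nu_RE > 0, "nu_RE must be positive (or NA to derive)")

  if (length(msgs)) msgs else TRUE
}

.newRodParams <- function(values, provenance = character(), schema = .PARAMS_SCHEMA) {
  values <- values[names(.PARAM_FIELDS)[names(.PARAM_FIELDS) %in% names(values)]]
  ok <- .validateParamValues(values)
  if (!isTRUE(ok)) stop("invalid parameters: ", paste(ok, collapse = "; "))
  new("RodParams", values = values, provenance = provenance, schema = schema)
}

#' Load a parameter file
#'
#' Reads a YAML parameter file (flat key/value, units in comments), checks
#' that all required fields are present, that no unknown keys appear, and
#' that every invariant holds (positivity, \code{beta} in \[0,1\],
#' \code{K_cG_min <= K_cG_max}, phosphorylation-state vector lengths, ...).
#'
#' @param path path to a YAML parameter file.
#' @return a validated \linkS4class{RodParams}.
#' @export
loadParams <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  schema <- raw$schema %||% .PARAMS_SCHEMA
  prov <- unlist(raw$provenance) %||% character()
  raw$schema <- NULL
  raw$provenance <- NULL
  unknown <- setdiff(names(raw), names(.PARAM_FIELDS))
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  vals <- lapply(raw, function(x) as.numeric(unlist(x)))
  if ("nu_RE" %in% names(vals) && length(vals$nu_RE) == 0) vals$nu_RE <- NA_real_
  .newRodParams(vals, provenance = prov, schema = schema)
}

#' Save a parameter set
#'
#' Writes a \linkS4class{RodParams} back to YAML in the packaged file format;
#' \code{loadParams(saveParams(p, f))} reproduces \code{p} field by field.
#'
#' @param p a \linkS4class{RodParams}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
saveParams <- function(p, path) {
  stopifnot(is(p, "RodParams"))
  out <- c(list(schema = p@schema), p@values)
  if (length(p@provenance)) out$provenance <- as.list(p@provenance)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Default mouse-rod parameter set
#'
#' Returns the packaged default parameters for a wild-type mouse rod. Values
#' reconstructed from published mouse-rod measurements and model ranges;
#' each default carries a provenance note (see
#' \code{paramProvenance}).
#'
#' @return a validated \linkS4class{RodParams}.
#' @export
defaultParams <- function() {
  path <- system.file("extdata", "mouse_rod_params.yaml", package = "pepperberg")
  if (!nzchar(path)) stop("packaged default parameter file not found")
  loadParams(path)
}

#' @rdname tauD
#' @param name parameter key, e.g. \code{"alpha_max"}.
#' @export
setGeneric("param", function(object, name) standardGeneric("param"))

#' @rdname tauD
#' @export
setMethod("param", "RodParams", function(object, name) {
  if (!name %in% names(.PARAM_FIELDS))
    stop("unknown parameter field: ", name)
  object@values[[name]]
})

#' Modify parameter values
#'
#' Returns a new validated \linkS4class{RodParams} with the named fields
#' replaced. The input object is unchanged.
#'
#' @param p a \linkS4class{RodParams}.
#' @param ... \code{name = value} replacements.
#' @export
setParams <- function(p, ...) {
  repl <- list(...)
  unknown <- setdiff(names(repl), names(.PARAM_FIELDS))
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  v <- p@values
  for (nm in names(repl)) v[[nm]] <- as.numeric(repl[[nm]])
  .newRodParams(v, provenance = p@provenance, schema = p@schema)
}

#' Provenance notes of a parameter set
#'
#' @param p a \linkS4class{RodParams}.
#' @return data.frame with columns \code{field} and \code{provenance}.
#' @export
paramProvenance <- function(p) {
  data.frame(field = names(p@provenance),
             provenance = unname(p@provenance),
             row.names = NULL, stringsAsFactors = FALSE)
}

## Full per-state lambda_max vector, length n+1 (last entry 0).
lambdaMaxVector <- function(p) {
  v <- p@values
  n <- v$n_sites
  lam <- v$lambda_max
  if (length(lam) == 1) c(rep(lam, n), 0) else lam
}

## Per-state arrestin binding rates, length n+1: zero below 3 attached
## phosphates (state j carries j-1 phosphates), mu_max from state 4 on.
muVector <- function(p) {
  v <- p@values
  n <- v$n_sites
  j <- seq_len(n + 1)
  ifelse(j >= 4, v$mu_max, 0)
}

## Per-state transducin activation rates nu_j (1/s), length n+1.
nuVector <- function(p) {
  v <- p@values
  n <- v$n_sites
  w <- v$nu_per_state
  if (length(w) == 1) w <- rep(w, n + 1)
  v$nu_RT * w
}

#' Unit conversions between molecule counts and concentrations
#'
#' The well-stirred model refers every species to the cytosolic volume
#' \code{V_cyt}; a flash of \code{phi} photoisomerizations enters the model
#' as \code{phi / (602.214 * V_cyt)} uM of newly activated rhodopsin.
#'
#' @param phi molecule count (photoisomerizations).
#' @param p a \linkS4class{RodParams}.
#' @return concentration in uM (\code{phiToConc}) or molecules
#'   (\code{concToPhi}).
#' @export
phiToConc <- function(phi, p) phi / (.AVOGADRO_UM3 * param(p, "V_cyt"))

#' @rdname phiToConc
#' @param conc concentration in uM.
#' @export
concToPhi <- function(conc, p) conc * .AVOGADRO_UM3 * param(p, "V_cyt")

#' @rdname phiToConc
#' @param intensity flash strength in photons per square micrometre.
#' @export
flashToPhi <- function(intensity, p) intensity * param(p, "collecting_area")

`%||%` <- function(a, b) if (is.null(a)) b else a

## Cheap deterministic fingerprint of a parameter set.
paramsFingerprint <- function(p) {
  x <- unlist(p@values)
  sprintf("%08x", sum(as.integer(
    abs((x * seq_along(x)) %% 7919) * 1e4) %% 65536L) %% .Machine$integer.max)
}
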