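#' Default model configuration
#'
#' @return the fully resolved default configuration list.
#' @export
defaultConfig <- function() {
  list(
    marker = list(basis = logCubicBasis(), covariates = character()),
    visiting = list(scale = "gap",
                    features = character(),
                    assocM0 = TRUE, assocSlope = TRUE,
                    frailty = FALSE,
                    knots = 3L, boundary = NULL,
                    prevGapCenter = 0.15,
                    firstGapFromZero = FALSE),
    causes = list(),
    quadrature = list(kind = "GH", nodes = 7L, draws = 500L, seed = 1L,
                      prune = 1e-10),
    optim = list(maxit = 400L, reltol = 1e-9, gradTol = 1e-5),
    seed = 1L
  )
}

defaultCause <- function() {
  list(features = character(), assocM0 = TRUE, assocSlope = TRUE,
       knots = 1L, boundary = NULL)
}

mergeKeys <- function(user, defaults, where) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", where, "' must be a list")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    hint <- vapply(unknown, function(k) {
      near <- agrep(k, names(defaults), max.distance = 0.4, value = TRUE)
      if (length(near)) paste0(" (did you mean '", near[1], "'?)") else ""
    }, character(1))
    stop("unknown config key", if (length(unknown) > 1) "s", " in '", where,
         "': ", paste0(unknown, hint, collapse = ", "))
  }
  out <- defaults
  for (k in names(user)) out[[k]] <- user[[k]]
  out
}

#' Validate and normalize a model configuration
#'
#' Fills documented defaults, rejects unknown keys (suggesting the nearest
#' valid key), and checks for contradictory settings.  The resolved
#' configuration is embedded in every fit, simulation, and report artifact
#' for provenance.
#'
#' @param config a (possibly partial) configuration list; see
#'   [defaultConfig()] for the available keys.
#' @return the normalized configuration, with a stable `hash` attribute.
#' @export
validateConfig <- function(config = list()) {
  def <- defaultConfig()
  if (!is.list(config)) stop("config must be a list")
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    hint <- vapply(unknown, function(k) {
      near <- agrep(k, names(def), max.distance = 0.4, value = TRUE)
      if (length(near)) paste0(" (did you mean '", near[1], "'?)") else ""
    }, character(1))
    stop("unknown config key", if (length(unknown) > 1) "s", ": ",
         paste0(unknown, hint, collapse = ", "))
  }
  out <- def
  out$marker <- mergeKeys(config$marker, def$marker, "marker")
  out$visiting <- mergeKeys(config$visiting, def$visiting, "visiting")
  out$quadrature <- mergeKeys(config$quadrature, def$quadrature,
                              "quadrature")
  out$optim <- mergeKeys(config$optim, def$optim, "optim")
  if (!is.null(config$seed)) out$seed <- as.integer(config$seed)
  if (!is.null(config$causes)) {
    if (!is.list(config$causes)) stop("config$causes must be a list")
    out$causes <- lapply(seq_along(config$causes), function(k)
      mergeKeys(config$causes[[k]], defaultCause(),
                paste0("causes[[", k, "]]")))
    if (length(out$causes))
      names(out$causes) <- names(config$causes) %||%
        paste0("cause", seq_along(out$causes))
  }
  if (!inherits(out$marker$basis, "markerBasis"))
    stop("config$marker$basis must be a markerBasis object")
  if (!out$visiting$scale %in% c("gap", "calendar", "none"))
    stop("visiting$scale must be one of 'gap', 'calendar', 'none'")
  if (out$visiting$frailty && out$visiting$scale == "none")
    stop("contradictory settings: frailty requires a visiting submodel ",
         "(visiting$scale is 'none')")
  if (out$visiting$scale == "calendar" && out$visiting$firstGapFromZero)
    stop("contradictory settings: firstGapFromZero is a gap-scale option")
  if (!out$quadrature$kind %in% c("GH", "MC"))
    stop("quadrature$kind must be 'GH' or 'MC'")
  if (out$quadrature$nodes < 1L || out$quadrature$draws < 1L)
    stop("quadrature sizes must be positive")
  attr(out, "hash") <- configHash(out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable hash of a resolved configuration
#'
#' FNV-1a over the deparsed configuration (functions deparsed by body), so
#' that identical settings always hash identically across runs.
#'
#' @param config a configuration list.
#' @return an 8-character hexadecimal string.
#' @export
configHash <- function(config) {
  txt <- paste(deparse(config, control = c("keepNA", "keepInteger")),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
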