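# Demographic models: diploid size N_t, t = 0 at present increasing into the
# past, and the diploid selection model.

#' Constant-size demography
#' @param N0 diploid effective size.
#' @return A \linkS4class{Demography}.
#' @export
constantDemography <- function(N0) {
  new("Demography", N0 = as.numeric(N0), type = "constant",
      table = data.frame(), rate = 0, Nmin = 1)
}

#' Piecewise-constant demography
#'
#' @param breaks data.frame with columns \code{t} (generation at which the
#'   epoch starts, going into the past; first row must be t = 0) and
#'   \code{N} (diploid size during that epoch).
#' @return A \linkS4class{Demography}.
#' @export
piecewiseDemography <- function(breaks) {
  breaks <- as.data.frame(breaks)
  names(breaks)[1:2] <- c("t", "N")
  if (breaks$t[1] != 0) stop("first breakpoint must be at t = 0")
  if (is.unsorted(breaks$t, strictly = TRUE))
    stop("breakpoints must be strictly increasing in t")
  new("Demography", N0 = as.numeric(breaks$N[1]), type = "piecewise",
      table = breaks, rate = 0, Nmin = 1)
}

#' Exponential-growth demography
#'
#' Forward-in-time exponential growth at per-generation rate \code{rate}:
#' backward in time N_t = max(N0 * exp(-rate * t), Nmin).
#'
#' @param N0 present diploid size.
#' @param rate forward growth rate per generation.
#' @param Nmin floor on the ancient size.
#' @return A \linkS4class{Demography}.
#' @export
exponentialDemography <- function(N0, rate, Nmin = 100) {
  new("Demography", N0 = as.numeric(N0), type = "exponential",
      table = data.frame(), rate = as.numeric(rate), Nmin = as.numeric(Nmin))
}

#' Population size at time t
#' @param demog a \linkS4class{Demography}.
#' @param t generations before present (vectorized).
#' @param xLinked apply the X-linked effective-size multiplier 3/4.
#' @return diploid size N_t.
#' @export
sizeAt <- function(demog, t, xLinked = FALSE) {
  N <- switch(demog@type,
    constant = rep(demog@N0, length(t)),
    piecewise = {
      idx <- findInterval(t, demog@table$t)
      demog@table$N[pmax(idx, 1L)]
    },
    exponential = pmax(demog@N0 * exp(-demog@rate * t), demog@Nmin))
  if (xLinked) N <- 0.75 * N
  pmax(N, 1)
}

#' @export
setMethod("show", "Demography", function(object) {
  cat(sprintf("Demography (%s): N0 = %g\n", object@type, object@N0))
})

#' Selection model constructor
#'
#' @param s selection coefficient.
#' @param model "additive" gives genotype fitnesses (1, 1 + s/2, 1 + s).
#'   Use \code{s1}, \code{s2} directly for other schemes.
#' @param s1,s2 explicit genotype coefficients for AA and Aa.
#' @return A \linkS4class{SelectionModel}.
#' @export
selectionModel <- function(s, model = c("additive", "custom"),
                           s1 = NULL, s2 = NULL) {
  model <- match.arg(model)
  if (model == "additive") { s1 <- s; s2 <- s / 2 }
  else if (is.null(s1) || is.null(s2)) stop("custom model needs s1 and s2")
  new("SelectionModel", s = as.numeric(s), s1 = as.numeric(s1),
      s2 = as.numeric(s2))
}

#' @export
setMethod("show", "SelectionModel", function(object) {
  cat(sprintf("SelectionModel: s = %g (s1 = %g, s2 = %g)\n",
              object@s, object@s1, object@s2))
})
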