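## Bundled calcium-handling gene/parameter mapping and a surrogate model
## of mean intracellular Ca2+ concentration.

#' Calcium-handling parameters and their mapped genes
#'
#' The packaged mapping of 13 parameters of a CA1 pyramidal-cell
#' calcium-handling model (ion channel and pump conductances/rates,
#' receptor densities and permeabilities, with their published baseline
#' values and units) to the 65 analyzed human genes. Four further genes
#' (*ATP2B3*, *CACNA1F*, *GRIA3*, *KCND1*) belong to the mapping but are
#' flagged excluded because no gene rank was available for them; request
#' them with `includeExcluded = TRUE`.
#'
#' @param includeExcluded logical; also place the four excluded genes in
#'   their parameters' gene lists.
#' @return A [ParameterSet-class] with 13 parameters.
#' @examples
#' ps <- calciumParameters()
#' length(ps)                           # 13
#' sum(lengths(mappedGenes(ps)))        # 65
#' @export
calciumParameters <- function(includeExcluded = FALSE) {
  path <- system.file("extdata", "calcium_parameters.tsv",
                      package = "mbgsa", mustWork = TRUE)
  tab <- read.table(path, sep = "\t", header = TRUE, fill = TRUE,
                    quote = "", comment.char = "",
                    stringsAsFactors = FALSE, na.strings = NULL)
  splitGenes <- function(s) {
    s[is.na(s)] <- ""
    lapply(strsplit(s, ";", fixed = TRUE),
           function(g) g[nzchar(g)])
  }
  ps <- ParameterSet(tab$parameter, tab$baseline, tab$units,
                     genes = splitGenes(tab$genes),
                     excluded = splitGenes(tab$excluded_genes))
  if (includeExcluded)
    ps@genes <- mapply(c, ps@genes, ps@excluded, SIMPLIFY = FALSE)
  ps
}

# Surrogate coefficients: relative influence of each parameter on the
# mean-Ca2+ proxy. Influx/release parameters enter the numerator,
# efflux/repolarization parameters the denominator; NMDA permeability and
# SERCA uptake dominate their respective groups.
.surrogateInc <- c(gCaL = 0.10, gCaT = 0.05, mGR0 = 0.04, k7 = 0.04,
                   k9 = 0.04, gInsP3R = 0.12, PNMDA = 0.45, PAMPA = 0.08,
                   gNa = 0.08)
.surrogateDec <- c(gamma0 = 0.25, Vmax = 0.60, gKA = 0.10, gKDR = 0.10)

#' Surrogate model of mean intracellular calcium
#'
#' A smooth, strictly monotone surrogate standing in for a full
#' biophysical simulation of intracellular Ca\eqn{^{2+}} during an induced
#' transient: a rational function of the 13 baseline-scaled
#' calcium-handling parameters, strictly increasing in every
#' influx/release parameter (Ca channels, NMDA/AMPA permeability, IP3
#' receptor density, mGluR cascade rates, Na conductance) and strictly
#' decreasing in every efflux/repolarization parameter (plasma-membrane
#' pump rate, SERCA uptake amplitude, K channel conductances). NMDA
#' permeability carries the strongest positive influence and SERCA uptake
#' the strongest negative one. The functional form is
#' \deqn{0.75 \cdot \frac{\sum_i a_i \, p_i/b_i}{1 + \sum_j c_j \, p_j/b_j}}
#' with fixed coefficients (versioned with the package) and published
#' baselines \eqn{b}; at baseline input it returns exactly
#' `0.75 / 2.05` = 0.36585366.
#'
#' @param params named numeric vector with all 13 parameters of
#'   [calciumParameters()].
#' @return A single positive scalar ("mean Ca proxy", arbitrary units).
#' @examples
#' calciumSurrogate(baselines(calciumParameters()))  # 0.3658537
#' @export
calciumSurrogate <- function(params) {
  need <- c(names(.surrogateInc), names(.surrogateDec))
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  b <- baselines(calciumParameters())
  z <- as.numeric(params[need]) / b[need]
  names(z) <- need
  num <- sum(.surrogateInc * z[names(.surrogateInc)])
  den <- 1 + sum(.surrogateDec * z[names(.surrogateDec)])
  0.75 * num / den
}
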