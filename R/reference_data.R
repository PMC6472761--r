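#' Reference estimates from the motivating soybean progeny trial
#'
#' Published estimates from a multi-environment soybean trial (203 F2:4
#' progeny from 3 populations, evaluated at 2 locations in randomized
#' complete blocks with 3 replicates, for days to maturity `DM`, 100-seed
#' weight `SW` and seed yield per plot `SY`). These tables are shipped as
#' plain-text inputs for the package's exact-arithmetic checks: variance
#' components per model, trait grand means, single-trait model deviances with
#' likelihood-ratio statistics, AIC values, and the breeding values of the 30
#' progeny selected per model.
#'
#' @param name one of `"components"`, `"trait_means"`, `"deviance"`, `"aic"`,
#'   `"selection"`.
#' @return a data frame.
#' @examples
#' comp <- soybean_reference("components")
#' subset(comp, model == "FSTME" & trait == "DM")
#' @export
soybean_reference <- function(name = c("components", "trait_means", "deviance",
                                       "aic", "selection")) {
  name <- match.arg(name)
  path <- system.file("extdata", "soybean_reference", paste0(name, ".tsv"),
                      package = "mtmeval", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, colClasses = NA)
}
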