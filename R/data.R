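#' Fitted parameters of the reference patient cohort
#'
#' Reads the per-patient fitted parameter table shipped with the
#' package: patient id, number of standard TMZ cycles received, and the
#' fitted (P0, rho, alpha1, alpha2). For all patients the fixed
#' constants were K = 523.6 cm^3 and kappa = 1, with drug clearance
#' lam = 8.3184 day^-1 and per-dose concentration C0 = 0.6 ug/cm^3.
#'
#' @param file path to a delimited table with columns \code{id},
#'   \code{n_cycles}, \code{P0}, \code{rho}, \code{alpha1},
#'   \code{alpha2}; defaults to the in-package fixture.
#' @return A data.frame, one row per patient.
#' @export
patientTable <- function(file = system.file("extdata",
                                            "table1_patients.tsv",
                                            package = "lgoTMZ")) {
  d <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("id", "n_cycles", "P0", "rho", "alpha1", "alpha2")
  if (!all(need %in% names(d)))
    stop("patient table must have columns: ", paste(need, collapse = ", "))
  d
}

#' Patient parameters from a cohort table row
#'
#' @param table a data.frame as returned by \code{\link{patientTable}}.
#' @param id patient id to extract.
#' @param K,kappa fixed constants.
#' @return A \linkS4class{PatientParams}.
#' @export
patientFromTable <- function(table, id, K = 523.6, kappa = 1) {
  i <- match(id, table$id)
  if (is.na(i)) stop("no patient with id ", id)
  PatientParams(P0 = table$P0[i], rho = table$rho[i],
                alpha1 = table$alpha1[i], alpha2 = table$alpha2[i],
                K = K, kappa = kappa)
}
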