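## Synthetic patient cohort with genotype-linked expression and survival.

#' Simulate a patient cohort from variant calls
#'
#' Patients receive random subsets of the called variants as somatic
#' mutations. Per-gene expression is standard normal, shifted by
#' `expression_shift * sign(lnFC)` standard deviations for carriers of a
#' functional variant in that gene. Survival times are exponential with hazard
#' `base_hazard * exp(utmb_hazard * uTMB)` where uTMB counts the patient's
#' functional mutations; censoring times are independent uniform on
#' `[0, censor_max]`.
#'
#' @param config A [sim_config()] (supplies the seed).
#' @param calls Variant call table with `variant_id`, `gene`, `lnFC`,
#'   `functional` (see [call_functional()]); a `driver_role` column is carried
#'   through when present.
#' @param n_patients Number of patients.
#' @param mean_mutations Mean somatic mutations assigned per patient
#'   (Poisson; 0 gives every patient an empty mutation set).
#' @param expression_shift Expression shift (in SD units) for carriers of a
#'   functional variant.
#' @param utmb_hazard Log-hazard increase per unit uTMB (0 makes survival
#'   independent of uTMB).
#' @param base_hazard Baseline exponential hazard.
#' @param censor_max Upper bound of the uniform censoring time.
#' @param cohort Cohort label.
#' @return List with `mutations` (patient, variant_id), `expression`
#'   (patients x genes matrix), `survival` (patient, time, event, cohort) and
#'   `patients`.
#' @export
simulate_cohort <- function(config, calls, n_patients = 120L,
                            mean_mutations = 3, expression_shift = 1.5,
                            utmb_hazard = 0.3, base_hazard = 0.1,
                            censor_max = 30, cohort = "SIM") {
  stopifnot(inherits(config, "sim_config"))
  assert_that(n_patients >= 1, "n_patients must be >= 1")
  assert_that(mean_mutations >= 0, "mean_mutations must be >= 0")
  set.seed(stage_seed(config, 5L))
  patients <- sprintf("P%04d", seq_len(n_patients))
  genes <- sort(unique(calls$gene))

  n_mut <- rpois(n_patients, mean_mutations)
  n_mut <- pmin(n_mut, nrow(calls))
  mutations <- do.call(rbind, lapply(seq_len(n_patients), function(i) {
    if (n_mut[i] == 0) return(NULL)
    data.frame(patient = patients[i],
               variant_id = sample(calls$variant_id, n_mut[i]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(mutations)) {
    mutations <- data.frame(patient = character(0), variant_id = character(0))
  }

  expression <- matrix(rnorm(n_patients * length(genes)), n_patients,
                       dimnames = list(patients, genes))
  fun_calls <- calls[calls$functional, , drop = FALSE]
  if (nrow(mutations) && nrow(fun_calls)) {
    carried <- merge(mutations, fun_calls[, c("variant_id", "gene", "lnFC")],
                     by = "variant_id")
    for (j in seq_len(nrow(carried))) {
      expression[carried$patient[j], carried$gene[j]] <-
        expression[carried$patient[j], carried$gene[j]] +
        expression_shift * sign(carried$lnFC[j])
    }
  }

  utmb <- vapply(patients, function(p) {
    mv <- mutations$variant_id[mutations$patient == p]
    sum(mv %in% fun_calls$variant_id)
  }, numeric(1))
  haz <- base_hazard * exp(utmb_hazard * utmb)
  t_event <- rexp(n_patients, rate = haz)
  t_cens <- runif(n_patients, 0, censor_max)
  survival <- data.frame(
    patient = patients,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    cohort = cohort,
    stringsAsFactors = FALSE
  )
  list(mutations = mutations, expression = expression, survival = survival,
       patients = data.frame(patient = patients, cohort = cohort,
                             utmb_true = utmb, stringsAsFactors = FALSE))
}
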