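# Generators for marked point patterns with known clustering structure, and
# for survival-linked synthetic cohorts. These stand in for multiplex-IHC
# tissue data: every generator's spatial statistics are known (CSR has
# nK = 1; the shared-parent Thomas process has a closed-form cross-K; hard
# inhibition forces nK below 1), so the estimator and the downstream
# pipeline can be validated against ground truth.

empty_cells <- function() {
  df <- data.frame(x = numeric(0), y = numeric(0), cell_class = character(0),
                   stringsAsFactors = FALSE)
  for (m in MARKER_NAMES) df[[m]] <- integer(0)
  df
}

# rows of cells for one component: a cell class, or a marker flag on
# class "other" cells (macrophage-type populations carry flags, not classes)
component_cells <- function(x, y, component) {
  n <- length(x)
  cls <- if (component %in% CLASS_NAMES) component else "other"
  df <- data.frame(x = x, y = y, cell_class = rep(cls, n),
                   stringsAsFactors = FALSE)
  for (m in MARKER_NAMES) {
    df[[m]] <- if (identical(m, component)) rep(1L, n) else integer(n)
  }
  df
}

runif_in <- function(n, window) {
  list(x = stats::runif(n, window$x_min, window$x_max),
       y = stats::runif(n, window$y_min, window$y_max))
}

#' Simulate complete spatial randomness (CSR)
#'
#' Independent homogeneous Poisson processes, one per named component:
#' counts are Poisson(lambda * |W|) and positions uniform in the window.
#' Component names in tumor/stroma/other become cell classes; marker names
#' (cd68, cd163, cd206, pdl1) become flag-carrying cells of class "other".
#'
#' @param lambda named vector of intensities in cells per um^2, e.g.
#'   `c(tumor = 1e-3, cd68 = 3e-4)`.
#' @param window a [pp_window()].
#' @param roi_id,sample_id,patient_id,sample_role pattern identifiers.
#' @param seed optional integer seed (set for reproducibility).
#' @return An `mpp`.
#' @examples
#' p <- simulate_csr(c(tumor = 1e-3, cd68 = 1e-3), seed = 1)
#' nk25(p, "tumor", "cd68") # close to 1
#' @export
simulate_csr <- function(lambda, window = pp_window(), roi_id = "csr",
                         sample_id = roi_id, patient_id = sample_id,
                         sample_role = "primary", seed = NULL) {
  check_components(names(lambda))
  if (any(lambda < 0)) stop("intensities must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  A <- area_um2(window)
  parts <- lapply(names(lambda), function(comp) {
    n <- stats::rpois(1, lambda[[comp]] * A)
    pos <- runif_in(n, window)
    component_cells(pos$x, pos$y, comp)
  })
  marked_point_pattern(do.call(rbind, c(list(empty_cells()), parts)),
                       window, roi_id, sample_id, patient_id, sample_role)
}

check_components <- function(comps) {
  if (is.null(comps) || any(!nzchar(comps))) {
    stop("components must be named", call. = FALSE)
  }
  bad <- setdiff(comps, c(CLASS_NAMES, MARKER_NAMES))
  if (length(bad)) {
    stop("unknown component(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(comps)
}

#' Simulate a shared-parent Thomas cluster process
#'
#' Parents form a homogeneous Poisson process with intensity `kappa`,
#' simulated on the window dilated by `expand` on every side so that
#' clusters whose parents lie just outside the ROI still contribute — this
#' realizes the stationary Thomas process restricted to the window, the
#' process for which [analytic_thomas_cross_nk()] is the exact cross-K.
#' Each parent emits Poisson(`mu_ref`) reference-component offspring and
#' Poisson(`mu_target`) target-component offspring, displaced by an
#' isotropic Gaussian with standard deviation `sigma` per axis. Offspring
#' falling outside the window are discarded (not wrapped). Sharing parents
#' induces cross-type clustering.
#'
#' @param kappa parent intensity per um^2.
#' @param mu_ref,mu_target mean offspring per parent for each component.
#' @param sigma Gaussian dispersion in um.
#' @param expand parent-window dilation in um (default `4 * sigma`, beyond
#'   which a parent's chance of placing offspring inside is negligible).
#' @param ref_component,target_component component names as in
#'   [simulate_csr()] (defaults: tumor cells and CD68+ cells).
#' @inheritParams simulate_csr
#' @return An `mpp`; if no parents are realized, an empty pattern with a
#'   warning.
#' @export
simulate_shared_parent_thomas <- function(kappa, mu_ref, mu_target, sigma,
                                          expand = 4 * sigma,
                                          window = pp_window(),
                                          ref_component = "tumor",
                                          target_component = "cd68",
                                          roi_id = "thomas",
                                          sample_id = roi_id,
                                          patient_id = sample_id,
                                          sample_role = "primary",
                                          seed = NULL) {
  stopifnot(kappa > 0, mu_ref > 0, mu_target > 0, sigma > 0, expand >= 0)
  check_components(c(ref_component, target_component))
  if (!is.null(seed)) set.seed(seed)
  dil <- structure(list(x_min = window$x_min - expand,
                        x_max = window$x_max + expand,
                        y_min = window$y_min - expand,
                        y_max = window$y_max + expand),
                   class = "pp_window")
  n_parents <- stats::rpois(1, kappa * area_um2(dil))
  if (n_parents == 0) {
    warning("no parents realized; returning empty pattern", call. = FALSE)
    return(marked_point_pattern(empty_cells(), window, roi_id, sample_id,
                                patient_id, sample_role))
  }
  par_pos <- runif_in(n_parents, dil)
  offspring <- function(mu, component) {
    n_off <- stats::rpois(n_parents, mu)
    px <- rep(par_pos$x, n_off)
    py <- rep(par_pos$y, n_off)
    x <- px + stats::rnorm(length(px), 0, sigma)
    y <- py + stats::rnorm(length(py), 0, sigma)
    keep <- x >= window$x_min & x <= window$x_max &
            y >= window$y_min & y <= window$y_max
    component_cells(x[keep], y[keep], component)
  }
  cells <- rbind(offspring(mu_ref, ref_component),
                 offspring(mu_target, target_component))
  marked_point_pattern(cells, window, roi_id, sample_id, patient_id,
                       sample_role)
}

#' Analytic cross-type nK for the shared-parent Thomas process
#'
#' Closed form for the expected normalized cross-K between two offspring
#' types sharing Poisson(kappa) parents with Gaussian(sigma) dispersion:
#' \deqn{nK(r) = 1 + \frac{1 - e^{-r^2/(4\sigma^2)}}{\kappa \pi r^2}}
#' Used as the independent oracle for the estimator/generator pair.
#'
#' @param r radius, um, > 0.
#' @param kappa parent intensity per um^2, > 0.
#' @param sigma Gaussian dispersion, um, > 0.
#' @return Expected nK(r), > 1, decreasing in kappa and (for fixed r) in
#'   sigma.
#' @examples
#' analytic_thomas_cross_nk(25, 1e-4, 10) # 5.0255
#' @export
analytic_thomas_cross_nk <- function(r, kappa, sigma) {
  if (any(r <= 0) || any(kappa <= 0) || any(sigma <= 0)) {
    stop("r, kappa and sigma must be positive", call. = FALSE)
  }
  1 + (1 - exp(-r^2 / (4 * sigma^2))) / (kappa * pi * r^2)
}

#' Simulate cross-type inhibition (dispersion)
#'
#' Both components start as independent CSR; each target cell lying within
#' `d_inhibit` of any reference cell is then deleted with probability
#' `p_thin`. With `p_thin = 1` and `d_inhibit >= r` the cross-type nK(r) is
#' exactly 0; intermediate thinning gives nK between 0 and 1.
#'
#' @param lambda_ref,lambda_target CSR intensities per um^2.
#' @param d_inhibit inhibition radius, um, > 0.
#' @param p_thin deletion probability in `[0, 1]`.
#' @param ref_component,target_component component names as in
#'   [simulate_csr()].
#' @inheritParams simulate_csr
#' @return An `mpp`.
#' @export
simulate_cross_inhibition <- function(lambda_ref, lambda_target, d_inhibit,
                                      p_thin, window = pp_window(),
                                      ref_component = "tumor",
                                      target_component = "cd68",
                                      roi_id = "inhib", sample_id = roi_id,
                                      patient_id = sample_id,
                                      sample_role = "primary", seed = NULL) {
  stopifnot(d_inhibit > 0, p_thin >= 0, p_thin <= 1,
            lambda_ref >= 0, lambda_target >= 0)
  check_components(c(ref_component, target_component))
  if (!is.null(seed)) set.seed(seed)
  A <- area_um2(window)
  rp <- runif_in(stats::rpois(1, lambda_ref * A), window)
  tp <- runif_in(stats::rpois(1, lambda_target * A), window)
  if (length(tp$x) > 0 && length(rp$x) > 0 && p_thin > 0) {
    d2 <- outer(tp$x, rp$x, "-")^2 + outer(tp$y, rp$y, "-")^2
    near <- apply(d2 <= d_inhibit^2, 1, any)
    drop <- near & stats::runif(length(tp$x)) < p_thin
    tp$x <- tp$x[!drop]; tp$y <- tp$y[!drop]
  }
  cells <- rbind(component_cells(rp$x, rp$y, ref_component),
                 component_cells(tp$x, tp$y, target_component))
  marked_point_pattern(cells, window, roi_id, sample_id, patient_id,
                       sample_role)
}

#' Simulate a survival-linked synthetic cohort
#'
#' Emulates the structure of a multiplex-IHC study of metastatic ccRCC:
#' patients contribute a primary tumor sample (and optionally a metastasis
#' sample) with several tumor-stroma-interface ROIs each, and overall
#' survival depends on a latent patient-level clustering covariate.
#'
#' Per patient, a standardized latent clustering level z maps to the Thomas
#' dispersion `sigma_i = sigma_mid * exp(-sigma_slope * z)` (small sigma =
#' tight clusters = high nK), so tumor/CD68+ clustering varies across
#' patients while CD68+ density stays roughly constant — density instead
#' gets an independent lognormal patient factor, keeping the two metrics
#' near-orthogonal. Each ROI superimposes a shared-parent Thomas pattern
#' (tumor cells + CD68+ cells) on CSR stroma and CSR CD163+/CD206+/PD-L1+
#' populations (the latter two sparse, so some ROIs fail the eligibility
#' filter, as in real cohorts). Survival times are exponential with rate
#' `h0 * exp(beta * z)`, administratively censored at `horizon` months.
#'
#' @param n_patients number of patients (>= 2).
#' @param rois_per_patient ROIs per sample.
#' @param p_metastasis probability a patient contributes an additional
#'   metastasis sample (excluded from survival analysis downstream).
#' @param kappa,mu_tumor,mu_cd68 Thomas parameters shared by all ROIs
#'   (CD68 offspring mean is scaled by the patient density factor).
#' @param sigma_mid,sigma_slope latent-to-dispersion map (um); sigma is
#'   clamped to `[4, 100]` um.
#' @param lambda_stroma,lambda_cd163,lambda_cd206,lambda_pdl1 CSR
#'   intensities per um^2 for the remaining populations.
#' @param density_sdlog SD of the log patient density factor for CD68.
#' @param beta log hazard ratio per SD of the latent clustering covariate.
#' @param h0 baseline hazard per month.
#' @param horizon administrative censoring horizon, months.
#' @param age_mean,age_sd,imdc_probs clinical covariate distributions
#'   (IMDC levels "1", "2", "3+").
#' @param window ROI window.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return A list with `cells` (one row per cell, schema of
#'   [write_cells_csv()]), `clinical` (patient_id, age, imdc, os_months,
#'   event), and `truth` (patient_id, z, sigma, density_factor) for
#'   validation.
#' @export
simulate_cohort <- function(n_patients = 35, rois_per_patient = 3,
                            p_metastasis = 13 / 35,
                            kappa = 1e-4, mu_tumor = 20, mu_cd68 = 3,
                            sigma_mid = 20, sigma_slope = 0.5,
                            lambda_stroma = 2e-3, lambda_cd163 = 3e-5,
                            lambda_cd206 = 1e-5, lambda_pdl1 = 1e-4,
                            density_sdlog = 0.25,
                            beta = log(2), h0 = 0.03, horizon = 60,
                            age_mean = 58, age_sd = 9,
                            imdc_probs = c("1" = 0.37, "2" = 0.49, "3+" = 0.14),
                            window = pp_window(), seed = NULL) {
  stopifnot(n_patients >= 2, rois_per_patient >= 1, h0 > 0, horizon > 0)
  if (!is.null(seed)) set.seed(seed)
  z <- as.numeric(scale(stats::rnorm(n_patients)))  # standardized latent
  sigma <- pmin(pmax(sigma_mid * exp(-sigma_slope * z), 4), 100)
  dens_factor <- exp(stats::rnorm(n_patients, 0, density_sdlog))
  has_met <- stats::runif(n_patients) < p_metastasis
  age <- round(stats::rnorm(n_patients, age_mean, age_sd))
  imdc <- sample(names(imdc_probs), n_patients, replace = TRUE,
                 prob = imdc_probs)
  t_event <- stats::rexp(n_patients, rate = h0 * exp(beta * z))
  event <- as.integer(t_event <= horizon)
  os_months <- pmin(t_event, horizon)

  all_cells <- vector("list", n_patients * (rois_per_patient * 2))
  k <- 0L
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%03d", i)
    roles <- c("primary", if (has_met[i]) "metastasis")
    for (role in roles) {
      sid <- paste0(pid, "_", substr(role, 1, 3))
      for (j in seq_len(rois_per_patient)) {
        rid <- paste0(sid, "_roi", j)
        pat <- simulate_shared_parent_thomas(
          kappa, mu_tumor, mu_cd68 * dens_factor[i], sigma[i],
          window = window, roi_id = rid, sample_id = sid, patient_id = pid,
          sample_role = role)
        bg <- simulate_csr(
          c(stroma = lambda_stroma, cd163 = lambda_cd163,
            cd206 = lambda_cd206, pdl1 = lambda_pdl1),
          window = window, roi_id = rid, sample_id = sid, patient_id = pid,
          sample_role = role)
        cells <- rbind(pat$cells[names(pat$cells) != ".row"],
                       bg$cells[names(bg$cells) != ".row"])
        k <- k + 1L
        all_cells[[k]] <- data.frame(
          patient_id = pid, sample_id = sid, sample_role = role,
          roi_id = rid, x_um = cells$x, y_um = cells$y,
          cell_class = cells$cell_class, cells[MARKER_NAMES],
          stringsAsFactors = FALSE)
      }
    }
  }
  list(
    cells = do.call(rbind, all_cells[seq_len(k)]),
    clinical = data.frame(
      patient_id = sprintf("P%03d", seq_len(n_patients)),
      age = age, imdc = imdc, os_months = os_months, event = event,
      stringsAsFactors = FALSE),
    truth = data.frame(
      patient_id = sprintf("P%03d", seq_len(n_patients)),
      z = z, sigma = sigma, density_factor = dens_factor,
      stringsAsFactors = FALSE)
  )
}
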