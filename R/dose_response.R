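## Four-parameter logistic (4PL) dose-response fitting.
##
## Model (inhibition direction, Hill slope > 0, decreasing in dose x):
##   y(x) = bottom + (top - bottom) / (1 + (x / ec50)^hill)
## Induction fits (acrosome reaction) use the mirrored convention,
## increasing in dose. Fitting is ordinary nonlinear least squares on
## log10 concentration, replicates entered as individual points.

#' Geometric dilution series
#'
#' @param top_conc Highest concentration (default 10 uM).
#' @param n Number of points (>= 2; default 8).
#' @param factor Dilution factor between points (> 1; default 3).
#'
#' @return Descending concentrations `top_conc / factor^(0:(n-1))`.
#' @export
dilution_series <- function(top_conc = 10, n = 8L, factor = 3) {
  if (top_conc <= 0 || factor <= 1 || n < 2L) {
    stop("need top_conc > 0, factor > 1, n >= 2")
  }
  top_conc / factor^(0:(n - 1L))
}

#' Evaluate the 4PL curve
#'
#' @param conc Concentrations.
#' @param top,bottom,ec50,hill Curve parameters.
#' @param direction `"inhibition"` (decreasing in dose) or `"induction"`.
#'
#' @return Fitted responses.
#' @export
predict_4pl <- function(conc, top, bottom, ec50, hill,
                        direction = c("inhibition", "induction")) {
  direction <- match.arg(direction)
  frac <- 1 / (1 + (conc / ec50)^hill)   # 1 at low dose, 0 at high dose
  if (direction == "inhibition") bottom + (top - bottom) * frac
  else bottom + (top - bottom) * (1 - frac)
}

.rss_4pl <- function(par, conc, resp, direction) {
  sum((resp - predict_4pl(conc, par[["top"]], par[["bottom"]],
                          10^par[["log10_ec50"]], par[["hill"]],
                          direction))^2)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Ordinary nonlinear least squares (Levenberg-Marquardt, on log10 EC50)
#' with self-starting initial values: top and bottom from the extreme mean
#' responses, EC50 at the concentration whose mean response is nearest the
#' half-way level, Hill slope 1. Hill is bounded to (0, 10]. If the
#' optimiser fails the initial parameters are polished with Nelder-Mead and
#' the fit is returned with `converged = FALSE`.
#'
#' @param data `data.frame(conc_um, response)`; replicates are individual
#'   rows. At least 4 distinct positive concentrations are required.
#' @param direction `"inhibition"` for percent-of-control motility curves
#'   (response falls with dose), `"induction"` for AR percent-events curves.
#' @param max_iter Maximum optimiser iterations (default 500).
#'
#' @return A list of class `fourpl_fit`: `top`, `bottom`, `ec50`, `hill`,
#'   `rss`, `converged`, `direction`, `n`, plus the initial parameter RSS
#'   (`rss_init`).
#' @export
fit_4pl <- function(data, direction = c("inhibition", "induction"),
                    max_iter = 500L) {
  direction <- match.arg(direction)
  data <- as.data.table(data)
  stopifnot(all(c("conc_um", "response") %in% names(data)))
  data <- data[is.finite(conc_um) & is.finite(response) & conc_um > 0]
  if (uniqueN(data$conc_um) < 4L) {
    stop("need at least 4 distinct positive concentrations")
  }
  means <- data[, .(m = mean(response)), by = conc_um]
  top0 <- max(means$m)
  bottom0 <- min(means$m)
  mid <- (top0 + bottom0) / 2
  ec50_0 <- means$conc_um[which.min(abs(means$m - mid))]
  start <- c(top = top0, bottom = bottom0,
             log10_ec50 = log10(ec50_0), hill = 1)
  rss_init <- .rss_4pl(start, data$conc_um, data$response, direction)

  fit_par <- start
  converged <- FALSE
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      lower = c(top = -Inf, bottom = -Inf, log10_ec50 = -12, hill = 1e-6),
      upper = c(top = Inf, bottom = Inf, log10_ec50 = 12, hill = 10),
      fn = function(par) {
        data$response - predict_4pl(data$conc_um, par[["top"]], par[["bottom"]],
                                    10^par[["log10_ec50"]], par[["hill"]],
                                    direction)
      },
      control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                           ftol = 1e-12, ptol = 1e-12)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    fit_par <- setNames(coef(fit), names(start))
    converged <- fit$info %in% 1:3
  } else {
    ## fall back to a derivative-free polish of the initial values
    op <- optim(start, .rss_4pl, conc = data$conc_um, resp = data$response,
                direction = direction, method = "Nelder-Mead",
                control = list(maxit = 2000))
    fit_par <- setNames(op$par, names(start))
  }
  rss <- .rss_4pl(fit_par, data$conc_um, data$response, direction)
  if (rss > rss_init) {            # never worse than the initialization
    fit_par <- start
    rss <- rss_init
    converged <- FALSE
  }
  structure(list(top = unname(fit_par[["top"]]),
                 bottom = unname(fit_par[["bottom"]]),
                 ec50 = unname(10^fit_par[["log10_ec50"]]),
                 hill = unname(fit_par[["hill"]]),
                 rss = rss, rss_init = rss_init,
                 converged = converged, direction = direction,
                 n = nrow(data)),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("<4PL fit (%s): top %.4g, bottom %.4g, EC50 %.4g uM, hill %.4g, RSS %.4g%s>\n",
              x$direction, x$top, x$bottom, x$ec50, x$hill, x$rss,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Efficacy of a fitted dose-response curve
#'
#' For inhibition curves on the percent-of-control scale, efficacy is the
#' percent maximal reduction referenced to the DMSO anchor at 100%:
#' `100 - bottom`, clamped to [0, 100]. For induction curves it is the
#' fitted top, clamped likewise.
#'
#' @param fit A [fit_4pl()] result.
#' @param direction Defaults to the fit's own direction.
#'
#' @return Efficacy in percent.
#' @export
efficacy <- function(fit, direction = fit$direction) {
  direction <- match.arg(direction, c("inhibition", "induction"))
  val <- if (direction == "inhibition") 100 - fit$bottom else fit$top
  min(max(val, 0), 100)
}

#' Fit 4PL curves for a table of compounds
#'
#' @param data `data.frame(compound_id, conc_um, replicate, response)`.
#' @param direction As in [fit_4pl()].
#'
#' @return A `data.table` with one row per compound: `compound_id`, `top`,
#'   `bottom`, `ec50_um`, `hill`, `efficacy_pct`, `rss`, `converged`.
#' @export
fit_dose_response_table <- function(data, direction = c("inhibition", "induction")) {
  direction <- match.arg(direction)
  data <- as.data.table(data)
  rbindlist(lapply(split(data, by = "compound_id"), function(d) {
    f <- fit_4pl(d, direction = direction)
    data.table(compound_id = d$compound_id[1L], top = f$top, bottom = f$bottom,
               ec50_um = f$ec50, hill = f$hill, efficacy_pct = efficacy(f),
               rss = f$rss, converged = f$converged)
  }))
}
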