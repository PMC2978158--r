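# LP/MILP back end: SciPy's HiGHS solvers through reticulate. Lazy,
# cached; binds to the python on PATH unless the user configured
# reticulate themselves.
.ofx <- new.env(parent = emptyenv())

scipy_optimize <- function() {
  if (!is.null(.ofx$sp)) return(.ofx$sp)
  if (!reticulate::py_available(initialize = FALSE) &&
      !nzchar(Sys.getenv("RETICULATE_PYTHON"))) {
    py <- Sys.which("python3")
    if (!nzchar(py)) py <- Sys.which("python")
    if (nzchar(py)) Sys.setenv(RETICULATE_PYTHON = py)
  }
  .ofx$sp <- reticulate::import("scipy.optimize", delay_load = FALSE)
  .ofx$sp
}

lp_status <- function(code) {
  switch(as.character(code),
         "0" = "optimal", "1" = "iteration_limit", "2" = "infeasible",
         "3" = "unbounded", "error")
}

#' Solve a bounded linear program
#'
#' Internal workhorse: maximize or minimize `obj . v` subject to
#' `A_eq v = b_eq`, `A_ub v <= b_ub` and `lb <= v <= ub`, using HiGHS.
#' Solver failure is reported distinctly from infeasibility via the
#' `status` field.
#'
#' @param obj objective coefficient vector.
#' @param A_eq,b_eq equality constraints (matrix may be dense or sparse;
#'   `NULL` for none).
#' @param A_ub,b_ub inequality constraints (`<=`), optional.
#' @param lb,ub variable bounds.
#' @param sense `"max"` or `"min"`.
#' @return list with `status` (`optimal`, `infeasible`, `unbounded`,
#'   `error`), `objective` and solution vector `x`.
#' @keywords internal
lp_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                     lb, ub, sense = c("max", "min")) {
  sense <- match.arg(sense)
  sp <- scipy_optimize()
  cvec <- if (sense == "max") -obj else obj
  bounds <- cbind(lb, ub)
  args <- list(c = cvec, bounds = bounds, method = "highs")
  if (!is.null(A_eq)) {
    args$A_eq <- as.matrix(A_eq)
    args$b_eq <- b_eq
  }
  if (!is.null(A_ub)) {
    args$A_ub <- as.matrix(A_ub)
    args$b_ub <- b_ub
  }
  res <- do.call(sp$linprog, args)
  status <- lp_status(res$status)
  x <- if (status == "optimal") as.numeric(res$x) else rep(NA_real_, length(obj))
  objective <- if (status == "optimal") {
    if (sense == "max") -res$fun else res$fun
  } else NA_real_
  list(status = status, objective = objective, x = x)
}

#' Solve a mixed-integer linear program
#'
#' Minimizes `obj . v` subject to `lb_con <= A v <= ub_con`, variable
#' bounds, and integrality on the flagged variables, using HiGHS
#' branch-and-bound.
#'
#' @param obj objective coefficients.
#' @param A constraint matrix.
#' @param con_lb,con_ub constraint lower/upper limits (use `-Inf`/`Inf`
#'   for one-sided rows).
#' @param lb,ub variable bounds.
#' @param integer logical vector flagging integer variables.
#' @return list with `status`, `objective`, `x`.
#' @keywords internal
milp_solve <- function(obj, A, con_lb, con_ub, lb, ub, integer) {
  sp <- scipy_optimize()
  constraints <- sp$LinearConstraint(as.matrix(A), con_lb, con_ub)
  bounds <- sp$Bounds(lb = lb, ub = ub)
  res <- sp$milp(c = obj, constraints = constraints, bounds = bounds,
                 integrality = as.numeric(integer))
  status <- lp_status(res$status)
  x <- if (status == "optimal") as.numeric(res$x) else rep(NA_real_, length(obj))
  objective <- if (status == "optimal") res$fun else NA_real_
  list(status = status, objective = objective, x = x)
}
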