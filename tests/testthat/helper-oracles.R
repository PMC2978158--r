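# Shared fixtures and independent oracles used across the suite.

# one default synthetic reconstruction, generated once per test run
GEN <- generate_source_model(synthetic_spec(seed = 42))

# build a metabolic_model from a reaction list given as equations
model_from_equations <- function(rxns, objective = NA_character_, id = "toy") {
  df <- do.call(rbind, lapply(rxns, function(r) {
    data.frame(id = r$id, lb = r$lb %||% NA_real_, ub = r$ub %||% NA_real_,
               gpr = r$gpr %||% "", subsystem = r$subsystem %||% "",
               equation = r$eq, stringsAsFactors = FALSE)
  }))
  parsed <- lapply(df$equation, parse_equation)
  revs <- vapply(parsed, `[[`, logical(1), "reversible")
  df$lb[is.na(df$lb)] <- ifelse(revs, -1000, 0)[is.na(df$lb)]
  df$ub[is.na(df$ub)] <- 1000
  met_ids <- sort(unique(unlist(lapply(parsed, function(p) names(p$stoich)))))
  S <- matrix(0, length(met_ids), nrow(df), dimnames = list(met_ids, df$id))
  for (k in seq_along(parsed)) S[names(parsed[[k]]$stoich), k] <- parsed[[k]]$stoich
  genes <- sort(unique(unlist(lapply(df$gpr, function(g) gpr_genes(parse_gpr(g))))))
  metabolic_model(genes = data.frame(id = genes),
                  mets = data.frame(id = met_ids),
                  rxns = df[, c("id", "lb", "ub", "gpr", "subsystem")],
                  S = S, objective = objective, id = id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# linear chain: EX -> uptake a, convert a -> b, biomass consumes b
chain_model <- function(uptake = 10, internal_ub = 1000) {
  model_from_equations(list(
    list(id = "EX_a", eq = "a[e] <=>", lb = -uptake, ub = 1000),
    list(id = "T_a", eq = "a[e] -> a[c]"),
    list(id = "conv", eq = "a[c] -> b[c]", ub = internal_ub, gpr = "g1"),
    list(id = "biomass", eq = "b[c] ->")
  ), objective = "biomass")
}

# ---- independent GPR oracle: R's own boolean evaluator --------------------
eval_rule_r <- function(rule, present) {
  if (is.null(rule) || !nzchar(rule)) return(TRUE)
  expr <- gsub("\\bor\\b", "||", gsub("\\band\\b", "&&", rule,
                                      ignore.case = TRUE), ignore.case = TRUE)
  ids <- unique(regmatches(rule, gregexpr("[A-Za-z_][A-Za-z0-9_]*", rule))[[1]])
  ids <- setdiff(ids, c("and", "or", "AND", "OR"))
  env <- new.env(parent = baseenv())
  for (g in ids) assign(g, g %in% present, envir = env)
  isTRUE(eval(parse(text = expr), envir = env))
}

# random GPR tree of bounded depth over the given genes, as a rule string
random_rule <- function(genes, depth = 3) {
  if (depth == 0 || runif(1) < 0.35) return(sample(genes, 1))
  op <- sample(c("and", "or"), 1)
  n <- sample(2:3, 1)
  kids <- vapply(seq_len(n), function(i) random_rule(genes, depth - 1), character(1))
  paste0("(", paste(kids, collapse = paste0(" ", op, " ")), ")")
}

# ---- vertex-enumeration LP oracle -----------------------------------------
# max obj.v subject to S v = 0, lb <= v <= ub (all bounds finite): the
# optimum of a bounded feasible LP is attained at a vertex, where n - rank(S)
# variables sit at a bound. Enumerates all such candidate vertices.
lp_vertex_oracle <- function(obj, S, lb, ub, tol = 1e-7) {
  S <- as.matrix(S)
  n <- length(obj)
  r <- qr(S)$rank
  k <- n - r
  best <- -Inf
  combos <- if (k == 0) list(integer(0)) else utils::combn(n, k, simplify = FALSE)
  for (N in combos) {
    B <- setdiff(seq_len(n), N)
    SB <- S[, B, drop = FALSE]
    qrB <- qr(SB)
    if (qrB$rank < length(B)) next
    n_masks <- if (length(N) == 0) 1L else 2L^length(N)
    for (mask in seq_len(n_masks) - 1L) {
      pick_ub <- if (length(N)) bitwAnd(mask, 2L^(seq_along(N) - 1L)) > 0 else logical(0)
      vN <- ifelse(pick_ub, ub[N], lb[N])
      rhs <- if (length(N)) -S[, N, drop = FALSE] %*% vN else matrix(0, nrow(S), 1)
      vB <- tryCatch(qr.coef(qrB, rhs), error = function(e) NULL)
      if (is.null(vB) || anyNA(vB)) next
      v <- numeric(n)
      v[N] <- vN
      v[B] <- vB
      if (max(abs(S %*% v)) > tol) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      best <- max(best, sum(obj * v))
    }
  }
  best
}

# random small flux network with finite bounds (zero flux always feasible)
random_small_network <- function(n_mets = 4, n_rxns = 7) {
  repeat {
    S <- matrix(0, n_mets, n_rxns)
    for (j in seq_len(n_rxns)) {
      rows <- sample(n_mets, sample(1:2, 1))
      S[rows, j] <- sample(c(-2, -1, 1, 2), length(rows), replace = TRUE)
    }
    if (all(rowSums(S != 0) > 0)) break
  }
  rev <- runif(n_rxns) < 0.4
  lb <- ifelse(rev, -10, 0)
  ub <- rep(10, n_rxns)
  mets <- sprintf("m%d[c]", seq_len(n_mets))
  rxns <- sprintf("R%d", seq_len(n_rxns))
  dimnames(S) <- list(mets, rxns)
  model <- metabolic_model(genes = data.frame(id = character(0)),
                           mets = data.frame(id = mets),
                           rxns = data.frame(id = rxns, lb = lb, ub = ub),
                           S = S, objective = NA_character_)
  list(model = model, S = S, lb = lb, ub = ub)
}

# ---- from-scratch knockout oracle -----------------------------------------
# rebuilds each knockout LP directly from the rule strings (independent GPR
# evaluation) and solves it with the raw LP bridge
essentiality_oracle <- function(model, threshold = 1e-6) {
  genes <- sort(model$genes$id)
  vapply(genes, function(g) {
    present <- setdiff(model$genes$id, g)
    lb <- model$rxns$lb
    ub <- model$rxns$ub
    off <- !vapply(model$rxns$gpr, eval_rule_r, logical(1), present = present)
    lb[off] <- 0
    ub[off] <- 0
    jobj <- match(model$objective, model$rxns$id)
    obj <- numeric(nrow(model$rxns))
    obj[jobj] <- 1
    res <- orthoflux:::lp_solve(obj, A_eq = model$S,
                                b_eq = numeric(nrow(model$S)),
                                lb = lb, ub = ub, sense = "max")
    opt <- if (res$status == "optimal") res$objective else 0
    opt < threshold
  }, logical(1))
}
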