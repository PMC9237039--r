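#' Specify a directed acyclic graph for the piecewise SEM
#'
#' Edges are `"source->sink"` strings. The default graph is the climate ->
#' GPPmax -> SOS model: each of the five growing-season climate drivers
#' points at both GPPmax and SOS, and GPPmax points at SOS.
#'
#' @param edges character vector of `"source->sink"` edges.
#' @return a `sem_spec` list with `nodes`, `edges` (data.frame
#'   `from, to`), `exogenous`, and a topological node order.
#' @export
sem_spec <- function(edges = flux_sem_edges()) {
  parts <- strsplit(edges, "->", fixed = TRUE)
  stopifnot(all(lengths(parts) == 2))
  ed <- data.frame(from = vapply(parts, `[[`, "", 1),
                   to = vapply(parts, `[[`, "", 2))
  nodes <- unique(c(ed$from, ed$to))
  order <- topo_sort(nodes, ed)
  if (is.null(order)) stop("graph-error: edge set contains a cycle", call. = FALSE)
  structure(list(nodes = nodes, edges = ed,
                 exogenous = setdiff(nodes, ed$to), order = order),
            class = "sem_spec")
}

topo_sort <- function(nodes, edges) {
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(edges$to)
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  repeat {
    free <- names(indeg)[indeg == 0]
    if (length(free) == 0) break
    out <- c(out, free)
    for (f in free) indeg[edges$to[edges$from == f]] <-
        indeg[edges$to[edges$from == f]] - 1L
    indeg <- indeg[!names(indeg) %in% free]
    if (length(indeg) == 0) break
  }
  if (length(out) < length(nodes)) NULL else out
}

sem_parents <- function(spec, node) spec$edges$from[spec$edges$to == node]

#' Fit a piecewise structural equation model
#'
#' Local-estimation SEM: one linear regression per endogenous node on its
#' parents, coefficients standardized by the SD ratio
#' (`b * SD(x)/SD(y)`). Overall consistency of data and graph is judged
#' by Shipley's test of directed separation: the basis set of missing
#' relations (non-adjacent node pairs, excluding pairs of exogenous
#' variables whose association the model leaves free) is tested by
#' regressing the topologically later variable of each pair on the other
#' plus the union of both parent sets, and the claim p-values are
#' combined into Fisher's C = -2 sum(log p), chi-square with `2k` df. The
#' graph is consistent with the data when `fisher_p > 0.05`. A saturated
#' graph has an empty basis set; C is then reported as 0 with `df = 0`
#' and `fisher_p = NA` (flagged, not testable).
#'
#' @param data data.frame containing every node variable.
#' @param spec a [sem_spec()].
#' @return a `sem_result` list: `paths` (data.frame `from, to, estimate,
#'   se, p_value`, standardized), `r_squared` per endogenous node,
#'   `fisher_c, fisher_df, fisher_p`, `basis_set` (tested claims),
#'   `n`.
#' @export
fit_piecewise_sem <- function(data, spec = sem_spec()) {
  stopifnot(inherits(spec, "sem_spec"))
  miss <- setdiff(spec$nodes, names(data))
  if (length(miss))
    stop("invalid-config: variables missing from data: ",
         paste(miss, collapse = ", "), call. = FALSE)
  data <- data[stats::complete.cases(data[spec$nodes]), spec$nodes, drop = FALSE]
  endo <- setdiff(spec$nodes, spec$exogenous)
  paths <- list(); r2 <- setNames(numeric(length(endo)), endo)
  for (node in endo) {
    pa <- sem_parents(spec, node)
    X <- data[, pa, drop = FALSE]
    if (qr(scale(as.matrix(X)))$rank < length(pa))
      stop("collinearity: collinear parents of ", node, call. = FALSE)
    fit <- lm(stats::reformulate(pa, response = node), data = data)
    sm <- summary(fit)$coefficients
    sdy <- sd(data[[node]])
    sdx <- vapply(pa, function(v) sd(data[[v]]), numeric(1))
    paths[[node]] <- data.frame(
      from = pa, to = node,
      estimate = sm[pa, "Estimate"] * sdx / sdy,
      se = sm[pa, "Std. Error"] * sdx / sdy,
      p_value = sm[pa, "Pr(>|t|)"], row.names = NULL)
    r2[node] <- summary(fit)$r.squared
  }
  basis <- dsep_basis_set(spec)
  claims <- lapply(basis, function(cl) {
    ctrl <- unique(c(cl$conditioning))
    rhs <- c(cl$x, ctrl)
    fit <- lm(stats::reformulate(rhs, response = cl$y), data = data)
    p <- summary(fit)$coefficients[cl$x, "Pr(>|t|)"]
    data.frame(independence = paste(cl$x, "_||_", cl$y, "|",
                                    paste(ctrl, collapse = ",")),
               p_value = p)
  })
  claims <- if (length(claims)) do.call(rbind, claims) else
    data.frame(independence = character(0), p_value = numeric(0))
  k <- nrow(claims)
  C <- if (k > 0) -2 * sum(log(pmax(claims$p_value, 1e-300))) else 0
  structure(list(paths = do.call(rbind, paths), r_squared = r2,
                 fisher_c = C, fisher_df = 2L * k,
                 fisher_p = if (k > 0) pchisq(C, 2 * k, lower.tail = FALSE)
                            else NA_real_,
                 basis_set = claims, n = nrow(data)),
            class = "sem_result")
}

# Shipley basis set: one claim per non-adjacent ordered pair (earlier,
# later) in topological order, conditioning on the union of both parents;
# pairs of exogenous variables are excluded (their association is free)
dsep_basis_set <- function(spec) {
  adj <- paste(spec$edges$from, spec$edges$to)
  out <- list()
  ord <- spec$order
  for (i in seq_along(ord)) for (j in seq_along(ord)) {
    if (j <= i) next
    a <- ord[i]; b <- ord[j]
    if (paste(a, b) %in% adj || paste(b, a) %in% adj) next
    if (a %in% spec$exogenous && b %in% spec$exogenous) next
    out[[length(out) + 1]] <- list(
      x = a, y = b,
      conditioning = unique(c(sem_parents(spec, a), sem_parents(spec, b))))
  }
  out
}

#' @export
print.sem_result <- function(x, ...) {
  cat("piecewise SEM (n =", x$n, ")\n")
  print(transform(x$paths, estimate = round(estimate, 3),
                  se = round(se, 3), p_value = signif(p_value, 3)))
  cat(sprintf("Fisher's C = %.3f, df = %d, p = %s\n", x$fisher_c,
              x$fisher_df,
              if (is.na(x$fisher_p)) "NA (saturated graph, df = 0)"
              else signif(x$fisher_p, 3)))
  invisible(x)
}

#' Direct, indirect and total effects of each climate driver on SOS
#'
#' Path-rule decomposition from a fitted SEM on the default graph: the
#' indirect effect of a climate driver is the product of its path into
#' the mediator (GPPmax) and the mediator's path into SOS; the total is
#' direct + indirect.
#'
#' @param sem a `sem_result` from [fit_piecewise_sem()].
#' @param mediator,response node names (defaults `"gppmax"`, `"sos"`).
#' @return data.frame `variable, direct, indirect, total`.
#' @export
direct_vs_indirect_effects <- function(sem, mediator = "gppmax",
                                       response = "sos") {
  p <- sem$paths
  med_path <- p$estimate[p$from == mediator & p$to == response]
  stopifnot(length(med_path) == 1)
  clim <- setdiff(unique(p$from[p$to == response]), mediator)
  direct <- vapply(clim, function(v)
    p$estimate[p$from == v & p$to == response], numeric(1))
  into_med <- vapply(clim, function(v) {
    e <- p$estimate[p$from == v & p$to == mediator]
    if (length(e)) e else 0
  }, numeric(1))
  indirect <- into_med * med_path
  data.frame(variable = clim, direct = direct, indirect = indirect,
             total = direct + indirect, row.names = NULL)
}

#' Z-score panel columns within site, then pool
#'
#' The SEM and random-forest inputs are standardized the same way the
#' anomaly analyses are built: each numeric column is z-scored within
#' site (removing between-site level differences), then rows are pooled
#' across sites.
#'
#' @param panel data.frame with a `site_id` column.
#' @param cols columns to standardize (default: all numeric except
#'   `year`).
#' @return the panel with standardized columns.
#' @export
standardize_panel <- function(panel, cols = NULL) {
  if (is.null(cols))
    cols <- setdiff(names(panel)[vapply(panel, is.numeric, logical(1))], "year")
  for (cl in cols) {
    panel[[cl]] <- stats::ave(panel[[cl]], panel$site_id, FUN = function(v) {
      s <- sd(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) v * NA_real_ else (v - mean(v, na.rm = TRUE)) / s
    })
  }
  panel
}
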