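#' Multiple-test correction for edgewise p-values
#'
#' Adjusts a vector of edgewise p-values for multiple testing. Backbone
#' extraction tests every dyad with a defined p-value, so the familywise
#' error rate grows quickly with the number of tested dyads (see
#' [familywise_rate()]); adjusting the p-values controls this inflation.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method One of `"none"`, `"bonferroni"`, `"holm"`, `"BH"`, `"BY"`.
#' @return Adjusted p-values, in the original order, capped at 1.
#' @examples
#' adjust_pvalues(c(0.01, 0.04, 0.03), "holm")
#' @export
adjust_pvalues <- function(p, method = c("none", "bonferroni", "holm", "BH", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = method)
}

#' Familywise error rate of uncorrected edgewise tests
#'
#' The probability of at least one false-positive edge when `m` independent
#' dyads are each tested at level `alpha`: \eqn{1 - (1 - \alpha)^m}.
#'
#' @param m Number of tested dyads (positive integer).
#' @param alpha Edgewise significance level in (0, 1).
#' @return A probability.
#' @examples
#' familywise_rate(9678, 0.001)
#' @export
familywise_rate <- function(m, alpha) {
  if (length(m) != 1 || !is.finite(m) || m < 1 || m != round(m)) {
    abort("`m` must be a positive integer.")
  }
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).")
  }
  1 - (1 - alpha)^m
}

#' Extract a backbone from an edgewise p-value object
#'
#' Thresholds the p-values of a [`backbone_result`][disparity] at a
#' significance level. Unsigned extraction keeps a dyad as a (positive) edge
#' when its adjusted upper-tail p-value is strictly below `alpha`. Signed
#' extraction is two-tailed: a dyad becomes a `+1` edge when its adjusted
#' upper-tail p-value is below `alpha/2`, and a `-1` edge when its adjusted
#' lower-tail p-value is below `alpha/2`; the two tails are adjusted
#' separately over the same family of tests.
#'
#' The family size `m` is the number of dyads with a defined p-value: the
#' positive-weight dyads for unsigned extraction, and (for bipartite models,
#' which test every dyad) all dyads for signed extraction, so that
#' zero-weight pairs can appear as significantly weak negative edges.
#'
#' @param R A `backbone_result` as returned by a statistical model with
#'   `alpha = NULL`.
#' @param alpha Significance level in (0, 1).
#' @param signed Logical; extract a signed backbone.
#' @param mtc Multiple-test correction, see [adjust_pvalues()].
#' @return A [`backbone`][tidy.backbone] tibble with columns `from`, `to`,
#'   `sign`.
#' @examples
#' r <- disparity(toy_weighted(), alpha = NULL)
#' extract_backbone(r, alpha = 0.05)
#' @export
extract_backbone <- function(R, alpha, signed = FALSE,
                             mtc = c("none", "bonferroni", "holm", "BH", "BY")) {
  mtc <- match.arg(mtc)
  if (!inherits(R, "backbone_result")) {
    abort("`R` must be a backbone_result object (run a statistical model with alpha = NULL).")
  }
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).")
  }
  tab <- tibble::as_tibble(as.data.frame(R))
  if (signed && !"p_lower" %in% names(tab)) {
    abort("signed extraction requires lower-tail p-values.")
  }
  if (!signed) {
    tab <- tab[tab$weight > 0, , drop = FALSE]
  }
  p_up <- adjust_pvalues(tab$p_upper, mtc)
  if (signed) {
    p_lo <- adjust_pvalues(tab$p_lower, mtc)
    pos <- p_up < alpha / 2
    neg <- p_lo < alpha / 2
    edges <- tibble::tibble(
      from = c(tab$from[pos], tab$from[neg]),
      to = c(tab$to[pos], tab$to[neg]),
      sign = c(rep(1L, sum(pos)), rep(-1L, sum(neg)))
    )
  } else {
    keep <- p_up < alpha
    edges <- tibble::tibble(from = tab$from[keep], to = tab$to[keep],
                            sign = rep(1L, sum(keep)))
  }
  params <- attr(R, "params")
  params$m_tested <- nrow(tab)
  new_backbone(
    edges,
    nodes = attr(R, "nodes"),
    model = attr(R, "model"),
    params = params,
    orig_stats = attr(R, "orig_stats"),
    alpha = alpha, mtc = mtc, signed = signed,
    network_desc = attr(R, "network_desc"),
    citations = model_citations(attr(R, "model"))
  )
}

model_citations <- function(model) {
  switch(model,
    disparity = c(
      "Serrano, M. A., Boguna, M., & Vespignani, A. (2009). Extracting the multiscale backbone of complex weighted networks. Proceedings of the National Academy of Sciences, 106(16), 6483-6488."
    ),
    sdsm = c(
      "Neal, Z. P. (2014). The backbone of bipartite projections: Inferring relationships from co-authorship, co-sponsorship, co-attendance and other co-behaviors. Social Networks, 39, 84-97."
    ),
    fdsm = c(
      "Zweig, K. A., & Kaufmann, M. (2011). A systematic approach to the one-mode projection of bipartite graphs. Social Network Analysis and Mining, 1(3), 187-218.",
      "Strona, G., Nappo, D., Boccacci, F., Fattorini, S., & San-Miguel-Ayanz, J. (2014). A fast and unbiased procedure to randomize ecological binary matrices with fixed row and column totals. Nature Communications, 5, 4114."
    ),
    fixedrow = c(
      "Tumminello, M., Micciche, S., Lillo, F., Piilo, J., & Mantegna, R. N. (2011). Statistically validated networks in bipartite complex systems. PLOS ONE, 6(3), e17994."
    ),
    sparsify_lspar = c(
      "Satuluri, V., Parthasarathy, S., & Ruan, Y. (2011). Local graph sparsification for scalable clustering. Proceedings of the 2011 ACM SIGMOD International Conference on Management of Data, 721-732."
    ),
    sparsify_localdegree = c(
      "Hamann, M., Lindner, G., Meyerhenke, H., Staudt, C. L., & Wagner, D. (2016). Structure-preserving sparsification methods for social networks. Social Network Analysis and Mining, 6(1), 22."
    ),
    character()
  )
}

model_phrase <- function(model, params) {
  switch(model,
    global = sprintf("if its weight exceeded the global threshold of %g",
                     params$threshold),
    disparity = "using the disparity filter (Serrano, Boguna, & Vespignani, 2009)",
    sdsm = "using the stochastic degree sequence model (SDSM; Neal, 2014)",
    fdsm = sprintf("using the fixed degree sequence model (FDSM; Zweig & Kaufmann, 2011) with %d Monte-Carlo trials",
                   params$trials %||% NA_integer_),
    fixedrow = "using the fixed row sums (hypergeometric) model (Tumminello et al., 2011)",
    fixedcol = "using the fixed column sums model",
    fixedfill = "using the fixed fill model",
    sprintf("using the %s model", model)
  )
}

#' Narrative description of a backbone extraction
#'
#' Generates manuscript-ready text describing what was extracted and how much
#' the network was reduced, together with the citations for the model used.
#' Edge reduction is \eqn{100 (1 - E_b / E_0)} over undirected
#' positive-weight edges; connected-node reduction is
#' \eqn{100 (1 - N_b / N_0)} where N counts nodes of degree at least one.
#' Percentages are rounded to one decimal with a trailing ".0" trimmed.
#'
#' @param backbone A `backbone` object.
#' @return The narrative string (also printed when the extracting function is
#'   called with `narrative = TRUE`), with a `stats` attribute carrying the
#'   numeric reduction statistics.
#' @examples
#' bb <- disparity(toy_weighted(), alpha = 0.05)
#' cat(narrative_text(bb))
#' @export
narrative_text <- function(backbone) {
  if (!inherits(backbone, "backbone")) abort("`backbone` must be a backbone object.")
  st <- attr(backbone, "stats")
  if (st$n_edges_original == 0) abort("original network has no edges.")
  model <- attr(backbone, "model")
  params <- attr(backbone, "params")
  desc <- attr(backbone, "network_desc") %||%
    sprintf("a network containing %d nodes", st$n_nodes)
  alpha <- attr(backbone, "alpha")
  mtc <- attr(backbone, "mtc")
  signed <- isTRUE(attr(backbone, "signed"))

  if (startsWith(model, "sparsify")) {
    preset <- params$preset %||% "custom"
    body <- sprintf(
      "Specifically, we used %s with a sparsification exponent of %g.",
      switch(preset,
             lspar = "Satuluri et al.'s (2011) L-Spar model",
             localdegree = "Hamann et al.'s (2016) local degree model",
             sprintf("a custom score/normalize/filter plan (escore = %s, normalize = %s, filter = %s)",
                     params$escore, params$normalize, params$filter)),
      params$s %||% NA_real_)
  } else if (is.null(alpha)) {
    body <- sprintf("An edge was retained in the backbone %s.",
                    model_phrase(model, params))
  } else {
    tail_txt <- if (signed) {
      sprintf("statistically significantly strong (retained as positive) or weak (retained as negative) in a two-tailed test (alpha = %g)", alpha)
    } else {
      sprintf("statistically significant (alpha = %g)", alpha)
    }
    mtc_txt <- if (!is.null(mtc) && mtc != "none") {
      sprintf(" P-values were adjusted using the %s multiple-test correction.", mtc)
    } else ""
    body <- if (model == "global") {
      sprintf("An edge was retained in the backbone %s.", model_phrase(model, params))
    } else {
      sprintf("An edge was retained in the backbone if its weight was %s %s.%s",
              tail_txt, model_phrase(model, params), mtc_txt)
    }
  }

  txt <- paste0(
    "=== Suggested manuscript text and citations ===\n\n",
    sprintf("We extracted the unweighted%s backbone of %s. ",
            if (signed) ", signed" else "", desc),
    body, "\n\n",
    sprintf("This reduced the number of edges by %s, and reduced the number of connected nodes by %s.\n",
            fmt_pct(st$edge_reduction_pct), fmt_pct(st$node_reduction_pct))
  )
  cites <- attr(backbone, "citations")
  if (length(cites)) txt <- paste0(txt, "\n", paste(cites, collapse = "\n\n"), "\n")
  structure(txt, stats = list(
    edge_reduction_pct = st$edge_reduction_pct,
    node_reduction_pct = st$node_reduction_pct
  ))
}
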