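#' Classification tree over SNP genotypes
#'
#' Binary recursive partitioning of a case-control sample on genotype
#' categories, in the classic CART style: each split divides one SNP's
#' observed genotype categories into two non-empty groups (all bipartitions
#' are candidates, so dominant-, recessive- and heterozygote-advantage-style
#' groupings can all be chosen), picked to maximise the decrease in Gini
#' impurity. Growth honours `min_split`, `min_bucket`, `max_depth` and a
#' complexity gate (a split is kept only when its sample-share-weighted
#' impurity decrease is at least `cp` times the root impurity). The grown
#' tree is then pruned by weakest-link cost-complexity pruning on
#' misclassification risk, either at a fixed complexity threshold
#' (`prune = "cp"`) or by the one-standard-error rule under
#' cross-validation (`prune = "one-se"`, the default).
#'
#' Individuals with a missing genotype at a split are sent with the
#' majority side of that split (no surrogate splits). Ties in impurity
#' decrease are broken deterministically by manifest SNP order, then by the
#' order in which bipartitions are enumerated (left set = single genotype
#' category, ascending code).
#'
#' @param ds a [genotype_dataset()].
#' @param min_split minimum node size to attempt a split (default 20).
#' @param min_bucket minimum child size (default 7).
#' @param cp complexity parameter (default 0.01).
#' @param max_depth maximum tree depth (default 30).
#' @param prune pruning rule: `"one-se"`, `"cp"` or `"none"`.
#' @param xval cross-validation folds for one-SE pruning (default 10).
#' @param seed RNG seed for the pruning cross-validation.
#' @return An object of class `"genotype_tree"`: list with `root` (nested
#'   node list), `full_root` (before pruning), `manifest`, `n`, `config`,
#'   and for one-SE pruning the CV risk table `cv_table`.
#' @seealso [terminal_nodes()], [terminal_node_report()],
#'   [predict.genotype_tree()]
#' @export
genotype_tree <- function(ds, min_split = 20, min_bucket = 7, cp = 0.01,
                          max_depth = 30, prune = c("one-se", "cp", "none"),
                          xval = 10, seed = 1) {
  prune <- match.arg(prune)
  if (min_bucket > min_split) stop("min_bucket must be <= min_split")
  y <- as.integer(ds$phenotype == "case")
  if (!any(y == 1) || !any(y == 0)) stop("dataset must contain both classes")
  X <- ds$genotypes
  cfg <- list(min_split = min_split, min_bucket = min_bucket, cp = cp,
              max_depth = max_depth, prune = prune, xval = xval, seed = seed)
  root <- grow_node(X, y, seq_len(nrow(X)), cfg, depth = 0L,
                    root_gini = gini_node(sum(y == 1), sum(y == 0)),
                    n_total = length(y))
  root <- number_nodes(root)
  out <- structure(list(root = root, full_root = root,
                        manifest = ds$manifest, n = length(y), config = cfg,
                        cv_table = NULL),
                   class = "genotype_tree")
  if (prune == "cp") {
    out$root <- number_nodes(prune_at(root, cp * tree_root_risk(root)))
  } else if (prune == "one-se") {
    pr <- one_se_prune(X, y, root, cfg)
    out$root <- number_nodes(pr$root)
    out$cv_table <- pr$cv_table
  }
  out
}

gini_node <- function(nc, nn) {
  n <- nc + nn
  if (n == 0) return(0)
  p <- nc / n
  2 * p * (1 - p)
}

# Enumerate candidate bipartitions of the observed genotype categories:
# each single category against the rest, ascending; with two observed
# categories there is one admissible split.
bipartitions <- function(observed) {
  observed <- sort(observed)
  if (length(observed) < 2) return(list())
  if (length(observed) == 2) return(list(list(left = observed[1],
                                              right = observed[2])))
  lapply(observed, function(o) list(left = o, right = setdiff(observed, o)))
}

# Best Gini split at a node: returns NULL or
# list(snp_j, left_codes, right_codes, missing_side, decrease (scaled)).
best_split <- function(X, y, idx, cfg, n_total) {
  nc <- sum(y[idx] == 1L); nn <- length(idx) - nc
  if (nc == 0L || nn == 0L) return(NULL)
  g_node <- gini_node(nc, nn)
  n_node <- length(idx)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    g <- X[idx, j]
    observed <- sort(unique(g[!is.na(g)]))
    for (part in bipartitions(observed)) {
      left <- !is.na(g) & g %in% part$left
      right <- !is.na(g) & g %in% part$right
      miss <- is.na(g)
      missing_side <- if (sum(right) > sum(left)) "right" else "left"
      if (any(miss)) {
        if (missing_side == "left") left <- left | miss else right <- right | miss
      }
      nl <- sum(left); nr <- sum(right)
      if (nl < cfg$min_bucket || nr < cfg$min_bucket) next
      ncl <- sum(y[idx][left] == 1L); ncr <- nc - ncl
      dec <- g_node - (nl / n_node) * gini_node(ncl, nl - ncl) -
        (nr / n_node) * gini_node(ncr, nr - ncr)
      dec_scaled <- (n_node / n_total) * dec
      if (is.null(best) || dec_scaled > best$decrease + 1e-12) {
        best <- list(snp_j = j, left_codes = part$left,
                     right_codes = part$right, missing_side = missing_side,
                     decrease = dec_scaled)
      }
    }
  }
  best
}

grow_node <- function(X, y, idx, cfg, depth, root_gini, n_total) {
  nc <- sum(y[idx] == 1L); nn <- length(idx) - nc
  node <- list(n_case = nc, n_control = nn, depth = depth, split = NULL,
               left = NULL, right = NULL)
  if (length(idx) < cfg$min_split || nc == 0L || nn == 0L ||
      depth >= cfg$max_depth)
    return(node)
  sp <- best_split(X, y, idx, cfg, n_total)
  if (is.null(sp) || sp$decrease < cfg$cp * root_gini - 1e-12) return(node)
  g <- X[idx, sp$snp_j]
  left <- (!is.na(g) & g %in% sp$left_codes) |
    (is.na(g) & sp$missing_side == "left")
  node$split <- sp
  node$left <- grow_node(X, y, idx[left], cfg, depth + 1L, root_gini, n_total)
  node$right <- grow_node(X, y, idx[!left], cfg, depth + 1L, root_gini, n_total)
  node
}

# Depth-first (pre-order) node numbering; leaves keep their ids stable
# under report/printing.
number_nodes <- function(root) {
  counter <- 0L
  walk <- function(node) {
    counter <<- counter + 1L
    node$id <- counter
    if (!is.null(node$split)) {
      node$left <- walk(node$left)
      node$right <- walk(node$right)
    }
    node
  }
  walk(root)
}

node_risk <- function(node) min(node$n_case, node$n_control)

subtree_stats <- function(node) {
  if (is.null(node$split))
    return(list(risk = node_risk(node), leaves = 1L))
  l <- subtree_stats(node$left); r <- subtree_stats(node$right)
  list(risk = l$risk + r$risk, leaves = l$leaves + r$leaves)
}

tree_root_risk <- function(root) node_risk(root)

# Weakest-link value g(t) for every internal node.
link_values <- function(node, acc = list()) {
  if (is.null(node$split)) return(acc)
  st <- subtree_stats(node)
  g <- (node_risk(node) - st$risk) / (st$leaves - 1L)
  acc[[length(acc) + 1L]] <- list(id = node$id, g = g)
  acc <- link_values(node$left, acc)
  link_values(node$right, acc)
}

collapse_nodes <- function(node, ids) {
  if (is.null(node$split)) return(node)
  if (node$id %in% ids) {
    node$split <- NULL; node$left <- NULL; node$right <- NULL
    return(node)
  }
  node$left <- collapse_nodes(node$left, ids)
  node$right <- collapse_nodes(node$right, ids)
  node
}

# Cost-complexity pruning: repeatedly collapse the internal node(s) with the
# smallest weakest-link value while that value is strictly below alpha
# (links costing exactly alpha are kept, so alpha = 0 is the identity).
prune_at <- function(root, alpha) {
  repeat {
    lv <- link_values(root)
    if (!length(lv)) return(root)
    gs <- vapply(lv, `[[`, numeric(1), "g")
    gm <- min(gs)
    if (gm >= alpha - 1e-9) return(root)
    root <- collapse_nodes(root,
                           vapply(lv, `[[`, integer(1), "id")[gs <= gm + 1e-9])
  }
}

# Alpha sequence of the nested pruning path (0 first, then each collapse
# threshold, strictly increasing).
alpha_sequence <- function(root) {
  alphas <- 0
  repeat {
    lv <- link_values(root)
    if (!length(lv)) break
    gs <- vapply(lv, `[[`, numeric(1), "g")
    gm <- min(gs)
    alphas <- c(alphas, gm)
    root <- collapse_nodes(root,
                           vapply(lv, `[[`, integer(1), "id")[gs <= gm + 1e-9])
  }
  unique(alphas)
}

# One-SE cost-complexity pruning: the alpha path comes from the tree grown
# on all data; per fold a tree is grown on the training part, pruned at the
# geometric mean of successive alphas and scored by misclassification on the
# held-out part; the chosen alpha is the largest one whose CV risk is within
# one standard error of the minimum.
one_se_prune <- function(X, y, root, cfg) {
  alphas <- alpha_sequence(root)
  if (length(alphas) == 1L)
    return(list(root = root, cv_table = NULL))
  betas <- c(sqrt(alphas[-length(alphas)] * alphas[-1]),
             alphas[length(alphas)] + 1)
  fold <- with_seed(cfg$seed, stratified_folds(y, cfg$xval))
  n <- length(y)
  errs <- matrix(0, max(fold), length(betas))
  for (f in seq_len(max(fold))) {
    tr <- fold != f
    froot <- number_nodes(grow_node(X[tr, , drop = FALSE], y[tr],
                                    seq_len(sum(tr)), cfg, 0L,
                                    gini_node(sum(y[tr] == 1), sum(y[tr] == 0)),
                                    sum(tr)))
    for (b in seq_along(betas)) {
      pruned <- prune_at(froot, betas[b])
      pred <- predict_nodes(pruned, X[!tr, , drop = FALSE], what = "class")
      errs[f, b] <- sum(pred != y[!tr])
    }
  }
  risk <- colSums(errs) / n
  se <- sqrt(risk * (1 - risk) / n)
  jmin <- which.min(risk)
  ok <- which(risk <= risk[jmin] + se[jmin])
  jsel <- max(ok)  # largest alpha = smallest tree within one SE
  cv_table <- data.frame(alpha = alphas, beta = betas, cv_risk = risk,
                         se = se, selected = seq_along(betas) == jsel)
  list(root = prune_at(root, betas[jsel]), cv_table = cv_table)
}

# Route rows of a genotype matrix down a tree. what = "leaf" gives leaf ids,
# "class" the leaf majority class (ties -> control, the larger group
# overall convention is not needed for scoring), "prob" the leaf case share.
predict_nodes <- function(root, X, what = c("leaf", "class", "prob")) {
  what <- match.arg(what)
  out <- if (what == "leaf") integer(nrow(X)) else numeric(nrow(X))
  route <- function(node, rows) {
    if (!length(rows)) return()
    if (is.null(node$split)) {
      out[rows] <<- switch(what,
                           leaf = node$id,
                           class = as.numeric(node$n_case > node$n_control),
                           prob = node$n_case / (node$n_case + node$n_control))
      return()
    }
    g <- X[rows, node$split$snp_j]
    left <- (!is.na(g) & g %in% node$split$left_codes) |
      (is.na(g) & node$split$missing_side == "left")
    route(node$left, rows[left])
    route(node$right, rows[!left])
  }
  route(root, seq_len(nrow(X)))
  out
}

#' Predict from a genotype classification tree
#'
#' @param object a `"genotype_tree"`.
#' @param newdata a [genotype_dataset()] or genotype code matrix with the
#'   training SNP columns.
#' @param type `"node"` (terminal node id), `"prob"` (training case share of
#'   the terminal node) or `"class"` (`control`/`case` by node majority).
#' @param ... unused.
#' @return Vector of predictions.
#' @export
predict.genotype_tree <- function(object, newdata,
                                  type = c("node", "prob", "class"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "genotype_dataset")) {
    newdata$genotypes[, object$manifest$snp_id, drop = FALSE]
  } else as.matrix(newdata)[, object$manifest$snp_id, drop = FALSE]
  switch(type,
         node = predict_nodes(object$root, X, "leaf"),
         prob = predict_nodes(object$root, X, "prob"),
         class = factor(ifelse(predict_nodes(object$root, X, "class") == 1,
                               "case", "control"),
                        levels = c("control", "case")))
}

#' Terminal nodes of a genotype tree
#'
#' @param tree a `"genotype_tree"`.
#' @return Data frame: `node` (id), `path` (human-readable genotype
#'   conditions), `n_case`, `n_control`, `case_fraction`.
#' @export
terminal_nodes <- function(tree) {
  m <- tree$manifest
  rows <- list()
  walk <- function(node, path) {
    if (is.null(node$split)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        node = node$id, path = if (length(path)) paste(path, collapse = " & ")
        else "<root>",
        n_case = node$n_case, n_control = node$n_control,
        case_fraction = node$n_case / (node$n_case + node$n_control))
      return()
    }
    sp <- node$split
    lab <- function(codes) paste(vapply(codes, function(cd)
      c(paste0(m$major[sp$snp_j], m$major[sp$snp_j]),
        paste0(m$major[sp$snp_j], m$minor[sp$snp_j]),
        paste0(m$minor[sp$snp_j], m$minor[sp$snp_j]))[cd + 1L],
      character(1)), collapse = "/")
    walk(node$left, c(path, paste0(m$snp_id[sp$snp_j], "=", lab(sp$left_codes))))
    walk(node$right, c(path, paste0(m$snp_id[sp$snp_j], "=", lab(sp$right_codes))))
  }
  walk(tree$root, character(0))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Risk table of terminal nodes against a reference node
#'
#' Orders terminal nodes by their case fraction, takes the node with the
#' lowest case fraction as the reference, and reports each node's odds
#' ratio (node vs reference, case vs control) with Woolf CI and
#' chi-square/Fisher p, plus a Cochran-Armitage trend test of case fraction
#' across the risk-ordered nodes (node rank as score).
#'
#' @param tree a `"genotype_tree"` with at least two terminal nodes.
#' @param reference `"lowest"` (lowest case fraction; ties broken by node
#'   id) or a terminal node id.
#' @param correction zero-cell handling for the ORs.
#' @return Data frame of class `"terminal_node_report"`, one row per node in
#'   ascending case-fraction order, with `or`, `ci_low`, `ci_high`,
#'   `p_value` (`NA` for the reference row); the trend p-value is attached
#'   as attribute `"p_trend"` (requires >= 3 nodes, else `NA`).
#' @export
terminal_node_report <- function(tree, reference = "lowest",
                                 correction = "none") {
  tn <- terminal_nodes(tree)
  if (nrow(tn) < 2) stop("need at least two terminal nodes")
  tn <- tn[order(tn$case_fraction, tn$node), ]
  ref_row <- if (identical(reference, "lowest")) 1L
  else match(reference, tn$node)
  if (is.na(ref_row)) stop("reference node id not found among terminal nodes")
  ref <- tn[ref_row, ]
  res <- lapply(seq_len(nrow(tn)), function(i) {
    if (i == ref_row)
      return(data.frame(or = 1, ci_low = NA_real_, ci_high = NA_real_,
                        defined = TRUE, p_value = NA_real_))
    tab <- two_by_two(tn$n_case[i], ref$n_case, tn$n_control[i], ref$n_control)
    r <- odds_ratio_ci(tab, correction = correction)
    r$p_value <- assoc_test(tab)
    r
  })
  out <- cbind(tn, do.call(rbind, res))
  rownames(out) <- NULL
  attr(out, "p_trend") <- if (nrow(out) >= 3)
    trend_test(out$n_case, out$n_case + out$n_control) else NA_real_
  attr(out, "reference") <- ref$node
  class(out) <- c("terminal_node_report", "data.frame")
  out
}

#' @export
print.terminal_node_report <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$case_fraction <- round(df$case_fraction, 3)
  for (cl in c("or", "ci_low", "ci_high", "p_value"))
    df[[cl]] <- signif(df[[cl]], digits)
  cat("Terminal-node risk table (reference node ", attr(x, "reference"),
      ", lowest case fraction)\n\n", sep = "")
  print(df, row.names = FALSE)
  cat("\nP trend (Cochran-Armitage across ordered nodes):",
      format.pval(attr(x, "p_trend"), digits = 3), "\n")
  invisible(x)
}

#' Cochran-Armitage trend test across ordered groups
#'
#' Two-sided trend test of event proportion across ordered groups with the
#' group rank as score (a thin wrapper over [stats::prop.trend.test()]).
#'
#' @param events event (case) counts per group, in order.
#' @param totals group sizes.
#' @param scores group scores; defaults to the rank `1..g`.
#' @return The two-sided p-value.
#' @export
trend_test <- function(events, totals, scores = seq_along(events)) {
  if (length(events) < 3) stop("trend test needs at least 3 ordered groups")
  suppressWarnings(stats::prop.trend.test(events, totals,
                                          score = scores)$p.value)
}

#' @export
print.genotype_tree <- function(x, ...) {
  cfg <- x$config
  cat("Genotype classification tree (", x$n, " individuals, prune = ",
      cfg$prune, ", cp = ", cfg$cp, ")\n", sep = "")
  m <- x$manifest
  walk <- function(node, indent, label) {
    frac <- node$n_case / (node$n_case + node$n_control)
    cat(indent, label, " n=", node$n_case + node$n_control,
        " (case ", node$n_case, "/control ", node$n_control,
        ", ", round(100 * frac, 1), "% case)",
        if (is.null(node$split)) " *" else "", "\n", sep = "")
    if (!is.null(node$split)) {
      sp <- node$split
      lab <- function(codes) paste(vapply(codes, function(cd)
        c(paste0(m$major[sp$snp_j], m$major[sp$snp_j]),
          paste0(m$major[sp$snp_j], m$minor[sp$snp_j]),
          paste0(m$minor[sp$snp_j], m$minor[sp$snp_j]))[cd + 1L],
        character(1)), collapse = "/")
      walk(node$left, paste0(indent, "  "),
           paste0(m$snp_id[sp$snp_j], "=", lab(sp$left_codes), ":"))
      walk(node$right, paste0(indent, "  "),
           paste0(m$snp_id[sp$snp_j], "=", lab(sp$right_codes), ":"))
    }
  }
  walk(x$root, "", "root:")
  invisible(x)
}

#' @export
summary.genotype_tree <- function(object, ...) {
  print(object)
  if (nrow(terminal_nodes(object)) >= 2) {
    cat("\n")
    print(terminal_node_report(object))
  }
  invisible(object)
}
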