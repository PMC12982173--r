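# Universal scoring: each raw parameter is positioned on a 0-100 point
# scale anchored on its normal range (mean M, SD sigma, side-specific
# extreme pathology bounds) by piecewise linear interpolation, then
# aggregated through a four-level hierarchy of unweighted means.

#' Normal-range anchors for one parameter
#'
#' @param parameter parameter name
#' @param M mean of the normal range (parameter units)
#' @param sigma SD of the normal range (> 0)
#' @param extreme_low,extreme_high extreme pathology bounds; must lie
#'   beyond `M - sigma` / `M + sigma` respectively
#' @param source `"literature"` or `"normative-database"`
#' @return object of class `norm_range`
#' @export
norm_range <- function(parameter, M, sigma, extreme_low, extreme_high,
                       source = "literature") {
  check_scalar(M, "M")
  check_scalar(sigma, "sigma", lower = 1e-12)
  check_scalar(extreme_low, "extreme_low")
  check_scalar(extreme_high, "extreme_high")
  if (!(extreme_low < M - sigma)) {
    stop("extreme_low must lie below M - sigma", call. = FALSE)
  }
  if (!(extreme_high > M + sigma)) {
    stop("extreme_high must lie above M + sigma", call. = FALSE)
  }
  source <- match.arg(source, c("literature", "normative-database"))
  structure(list(parameter = parameter, M = M, sigma = sigma,
                 extreme_low = extreme_low, extreme_high = extreme_high,
                 source = source),
            class = "norm_range")
}

#' Point anchors of the 0-100 scale
#'
#' The published system fixes only the 100-point interval scale; where the
#' mean and the norm boundary sit on it is configurable. Defaults: 100
#' points at the mean, 75 at the M +/- sigma boundary, 0 at the extreme
#' pathology bound.
#'
#' @param points_at_mean,points_at_norm_boundary,points_at_extreme
#'   anchor values; must satisfy
#'   `100 >= mean > boundary > extreme >= 0`
#' @return object of class `scale_anchors`
#' @export
scale_anchors <- function(points_at_mean = 100, points_at_norm_boundary = 75,
                          points_at_extreme = 0) {
  if (!(100 >= points_at_mean && points_at_mean > points_at_norm_boundary &&
        points_at_norm_boundary > points_at_extreme &&
        points_at_extreme >= 0)) {
    stop("anchors must satisfy 100 >= mean > boundary > extreme >= 0",
         call. = FALSE)
  }
  structure(list(points_at_mean = points_at_mean,
                 points_at_norm_boundary = points_at_norm_boundary,
                 points_at_extreme = points_at_extreme),
            class = "scale_anchors")
}

#' Map a raw parameter value to scale points
#'
#' Piecewise linear and symmetric in deviation direction, with
#' side-specific extremes: `points_at_mean` at `v = M`, linear down to
#' `points_at_norm_boundary` at one sigma from the mean, then linear down
#' to `points_at_extreme` at the extreme bound of that side; clamped to
#' [0, 100]. Missing input yields missing output.
#'
#' @param value raw value(s) in parameter units (vectorised)
#' @param norm a [norm_range()]
#' @param anchors a [scale_anchors()]
#' @return numeric points in [0, 100]
#' @export
scale_parameter <- function(value, norm, anchors = scale_anchors()) {
  stopifnot(inherits(norm, "norm_range"), inherits(anchors, "scale_anchors"))
  a_m <- anchors$points_at_mean
  a_b <- anchors$points_at_norm_boundary
  a_e <- anchors$points_at_extreme
  vapply(as.numeric(value), function(v) {
    if (is.na(v)) return(NA_real_)
    d <- abs(v - norm$M) / norm$sigma
    ext <- if (v >= norm$M) norm$extreme_high else norm$extreme_low
    d_ext <- abs(ext - norm$M) / norm$sigma  # > 1 by construction
    pts <- if (d <= 1) {
      a_m - (a_m - a_b) * d
    } else {
      a_b - (a_b - a_e) * (d - 1) / (d_ext - 1)
    }
    min(100, max(0, pts))
  }, numeric(1))
}

#' Build a four-level score hierarchy
#'
#' The tree has exactly four levels: leaves are individual parameters
#' (level 1), level 2 holds groups of related indicators, level 3 the
#' functional blocks (regulation, myocardial condition, arrhythmia,
#' psycho-emotional status), and the level-4 root is the general integral
#' indicator. Supply it as a nested named list:
#' `list(root = list(block = list(group = c("param1", "param2"))))`.
#'
#' @param tree nested named list; innermost elements are character vectors
#'   of parameter names
#' @return object of class `score_hierarchy`
#' @export
score_hierarchy <- function(tree) {
  if (!is.list(tree) || length(tree) != 1L || is.null(names(tree))) {
    stop("hierarchy must be a single named root node", call. = FALSE)
  }
  depth <- function(node) {
    if (is.character(node)) return(1L)
    if (!is.list(node) || !length(node)) {
      stop("empty node in hierarchy", call. = FALSE)
    }
    1L + max(vapply(node, depth, integer(1)))
  }
  if (depth(tree[[1L]]) != 3L) {
    stop("hierarchy must have exactly 4 levels ",
         "(root > blocks > groups > parameters)", call. = FALSE)
  }
  leaves <- unlist(tree, use.names = FALSE)
  if (!length(leaves)) stop("hierarchy has no leaves", call. = FALSE)
  structure(list(tree = tree, leaves = leaves), class = "score_hierarchy")
}

#' Aggregate leaf points through the hierarchy
#'
#' Every node's value is the arithmetic mean of its non-missing children;
#' a node is missing only if all its children are. The root is the
#' level-4 general integral indicator.
#'
#' @param hierarchy a [score_hierarchy()]
#' @param leaf_points named numeric vector of per-parameter points
#' @return named numeric vector of composite values, one per internal
#'   node (names are node names), root included
#' @export
aggregate_scores <- function(hierarchy, leaf_points) {
  stopifnot(inherits(hierarchy, "score_hierarchy"))
  out <- new.env(parent = emptyenv())
  eval_node <- function(node, name) {
    if (is.character(node)) {
      vals <- vapply(node, function(p) {
        v <- leaf_points[[p]] %||% NA_real_
        if (is.null(v)) NA_real_ else as.numeric(v)
      }, numeric(1))
    } else {
      vals <- vapply(seq_along(node), function(i) {
        eval_node(node[[i]], names(node)[i])
      }, numeric(1))
    }
    v <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    assign(name, v, envir = out)
    v
  }
  eval_node(hierarchy$tree[[1L]], names(hierarchy$tree)[1L])
  res <- unlist(as.list(out))
  res[order(names(res))]
}

#' Read / write the norm-range table CSV
#'
#' Columns: parameter, M, sigma, extreme_low, extreme_high, level2_group,
#' level3_block, source.
#'
#' @param path file path
#' @return data.frame of the table
#' @export
read_norm_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("parameter", "M", "sigma", "extreme_low", "extreme_high",
            "level2_group", "level3_block", "source")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("norm table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Default bundled norm-range table
#'
#' Literature-style normal ranges for the basic amplitude-time ECG
#' quantities plus ranges for HRV quantities regenerable from a synthetic
#' normative cohort (tagged "normative-database").
#' @return data.frame (see [read_norm_table()])
#' @export
default_norm_table <- function() {
  read_norm_table(system.file("extdata", "norm_ranges.csv",
                              package = "cardioscreen", mustWork = TRUE))
}

#' Validate a norm-range table row-wise
#'
#' @param path CSV path
#' @return data.frame of violations (row, parameter, problem); zero rows
#'   when the table is valid
#' @export
validate_norm_table <- function(path) {
  df <- read_norm_table(path)
  probs <- list()
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    note <- function(msg) {
      probs[[length(probs) + 1L]] <<-
        data.frame(row = i, parameter = as.character(r$parameter),
                   problem = msg)
    }
    if (!is.finite(r$sigma) || r$sigma <= 0) note("sigma must be > 0")
    else {
      if (is.finite(r$extreme_low) && !(r$extreme_low < r$M - r$sigma)) {
        note("extreme_low must be < M - sigma")
      }
      if (is.finite(r$extreme_high) && !(r$extreme_high > r$M + r$sigma)) {
        note("extreme_high must be > M + sigma")
      }
    }
    if (!r$source %in% c("literature", "normative-database")) {
      note("source must be literature or normative-database")
    }
  }
  if (!length(probs)) {
    return(data.frame(row = integer(0), parameter = character(0),
                      problem = character(0)))
  }
  do.call(rbind, probs)
}

#' Build the default hierarchy from a norm table
#'
#' Groups (level 2) and blocks (level 3) come from the table's
#' `level2_group` and `level3_block` columns; the root is the general
#' integral cardiovascular indicator.
#'
#' @param norm_table data.frame from [read_norm_table()] /
#'   [default_norm_table()]
#' @return a [score_hierarchy()]
#' @export
hierarchy_from_norm_table <- function(norm_table) {
  blocks <- split(norm_table, norm_table$level3_block)
  tree <- list(lapply(blocks, function(b) {
    lapply(split(b, b$level2_group), function(g) as.character(g$parameter))
  }))
  names(tree) <- "General integral indicator"
  score_hierarchy(tree)
}

#' Score a cohort feature table against a norm table
#'
#' Scales every feature that has a norm-range row, aggregates through the
#' hierarchy, and returns the feature table with per-node
#' `"<node> (composite index)"` columns appended.
#'
#' @param features data.frame with a `subject_id` column plus parameters
#' @param norm_table norm-range table (default bundled)
#' @param anchors a [scale_anchors()]
#' @param hierarchy a [score_hierarchy()]; default derived from the table
#' @return list with `scored` (the augmented data.frame) and
#'   `leaf_points` (subjects x parameters matrix of points)
#' @export
score_cohort <- function(features, norm_table = default_norm_table(),
                         anchors = scale_anchors(),
                         hierarchy = hierarchy_from_norm_table(norm_table)) {
  stopifnot(is.data.frame(features), "subject_id" %in% names(features))
  params <- intersect(norm_table$parameter, names(features))
  norms <- lapply(params, function(p) {
    r <- norm_table[norm_table$parameter == p, ][1L, ]
    norm_range(p, r$M, r$sigma, r$extreme_low, r$extreme_high,
               as.character(r$source))
  })
  names(norms) <- params
  n <- nrow(features)
  pts <- matrix(NA_real_, n, length(params),
                dimnames = list(features$subject_id, params))
  for (p in params) {
    pts[, p] <- scale_parameter(features[[p]], norms[[p]], anchors)
  }
  comp <- t(vapply(seq_len(n), function(i) {
    aggregate_scores(hierarchy, pts[i, ])
  }, numeric(length(aggregate_scores(hierarchy,
                                     stats::setNames(rep(NA_real_,
                                                         length(params)),
                                                     params))))))
  colnames(comp) <- paste0(colnames(comp), " (composite index)")
  scored <- cbind(features, as.data.frame(comp, check.names = FALSE))
  list(scored = scored, leaf_points = pts)
}

#' Write / read a score hierarchy as YAML
#' @param hierarchy a [score_hierarchy()]
#' @param path file path
#' @export
write_hierarchy_yaml <- function(hierarchy, path) {
  stopifnot(inherits(hierarchy, "score_hierarchy"))
  yaml::write_yaml(hierarchy$tree, path)
  invisible(path)
}

#' @rdname write_hierarchy_yaml
#' @export
read_hierarchy_yaml <- function(path) {
  score_hierarchy(yaml::read_yaml(path))
}
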