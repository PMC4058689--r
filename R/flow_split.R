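# Baseline (healthy) flow distribution among outlets by the generalized
# Murray's law: flow fractions proportional to outlet diameter to a power k.

#' Murray's-law flow split among outlets
#'
#' Distributes flow among outlets in proportion to `d_i^k / sum_j d_j^k`.
#' The classical Murray exponent is `k = 3`; the default `k = 7/3` is the
#' generalized value commonly fitted to epicardial coronary trees.
#'
#' @param outlet_diameters named numeric vector of outlet diameters (mm,
#'   all > 0); names are outlet ids.
#' @param exponent Murray exponent `k` (> 0).
#' @return An object of class `flow_split`: list with `fractions` (named,
#'   summing to 1) and `exponent`.
#' @examples
#' murray_split(c(a = 2, b = 1), exponent = 3)$fractions  # 8/9, 1/9
#' @export
murray_split <- function(outlet_diameters, exponent = 7 / 3) {
  if (is.null(names(outlet_diameters)) || any(!nzchar(names(outlet_diameters)))) {
    stop("outlet diameters must be named by outlet id", call. = FALSE)
  }
  if (any(outlet_diameters <= 0)) {
    stop("all outlet diameters must be > 0", call. = FALSE)
  }
  if (!is.numeric(exponent) || exponent <= 0) {
    stop("Murray exponent must be > 0", call. = FALSE)
  }
  w <- outlet_diameters^exponent
  structure(list(fractions = w / sum(w), exponent = exponent),
            class = "flow_split")
}

#' @export
print.flow_split <- function(x, ...) {
  cat(sprintf("<flow_split> k = %.4g\n", x$exponent))
  print(round(x$fractions, 4))
  invisible(x)
}

#' Murray split for a tree's outlets
#'
#' Convenience wrapper: reads each outlet's terminal diameter (at its distal
#' end) from the tree and applies [murray_split()].
#'
#' @param tree a [coronary_tree()].
#' @param exponent Murray exponent.
#' @return A `flow_split` covering exactly `tree$outlets`.
#' @export
tree_murray_split <- function(tree, exponent = 7 / 3) {
  d <- vapply(tree$outlets, function(id) {
    seg <- tree$segments[[id]]
    seg$profile[nrow(seg$profile), 2L]
  }, numeric(1))
  murray_split(d, exponent)
}

#' Assign baseline outlet flows from a split
#'
#' @param tree a [coronary_tree()].
#' @param split a `flow_split` whose fraction names are exactly the tree's
#'   outlets.
#' @param total_inflow_ml_min total inflow (mL/min).
#' @return Named numeric vector of outlet flows (mL/min) summing to the
#'   total inflow.
#' @examples
#' tree <- build_lad_tree()
#' q <- assign_baseline_flows(tree, tree_murray_split(tree), 66.75)
#' sum(q)  # 66.75
#' @export
assign_baseline_flows <- function(tree, split, total_inflow_ml_min) {
  stopifnot(inherits(split, "flow_split"))
  if (!setequal(names(split$fractions), tree$outlets)) {
    stop("flow split does not cover exactly the tree's outlets", call. = FALSE)
  }
  if (total_inflow_ml_min <= 0) {
    stop("total inflow must be > 0", call. = FALSE)
  }
  split$fractions[tree$outlets] * total_inflow_ml_min
}
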