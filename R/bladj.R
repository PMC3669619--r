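#' Create a calibration set for age interpolation
#'
#' @param ages named numeric vector: node label -> age (time before present;
#'   rootward ages are larger; 0 = present).
#' @param default_tip_age age assumed for tips not named in `ages`
#'   (default 0, i.e. extant taxa; fossil tips can be given nonzero ages).
#' @return an object of class `calibration_set`.
#' @export
calibration_set <- function(ages, default_tip_age = 0) {
  ages <- unlist(ages)
  if (is.null(names(ages)) || any(!nzchar(names(ages)))) {
    stop("calibration ages must be named by node label")
  }
  if (anyDuplicated(names(ages))) {
    stop("duplicate calibration labels: ",
         paste(unique(names(ages)[duplicated(names(ages))]), collapse = ", "))
  }
  if (any(!is.finite(ages) | ages < 0)) stop("calibration ages must be finite and >= 0")
  if (!is.finite(default_tip_age) || default_tip_age < 0) stop("invalid default_tip_age")
  structure(list(ages = ages, default_tip_age = default_tip_age),
            class = "calibration_set")
}

#' Read calibrations from a two-column text file
#'
#' Plain text, one `label<TAB>age` pair per line; lines starting with `#`
#' are ignored.
#'
#' @param file path to the calibration file.
#' @param default_tip_age as in [calibration_set()].
#' @return a `calibration_set`.
#' @export
read_calibrations <- function(file, default_tip_age = 0) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "[\t ]+")
  lab <- vapply(parts, `[`, character(1), 1)
  age <- as.numeric(vapply(parts, `[`, character(1), 2))
  calibration_set(stats::setNames(age, lab), default_tip_age = default_tip_age)
}

#' bladj-style node age interpolation
#'
#' Fixes the ages of calibrated nodes and assigns every other node an age so
#' that branchings are evenly spaced between the nearest fixed ages, then
#' sets each branch length to the parent-child age difference.
#'
#' The interpolation processes uncalibrated internal nodes from the root
#' down (so a node's parent age is already fixed when it is visited).  For
#' node `v` with parent age `a_top`, the nearest originally-fixed
#' descendants are found on every tipward chain; among them the one with the
#' most intervening nodes is chosen (ties broken toward the larger age), and
#' with `k` edges from `v` down to that descendant of age `a_bot`,
#'
#'   `age(v) = a_top - (a_top - a_bot) / (k + 1)`.
#'
#' On a chain between two fixed nodes this spaces the intermediate
#' branchings exactly evenly.  If an unchosen fixed descendant is older than
#' the interpolated age, the age is raised to it (never above `a_top`) so
#' that ages stay monotone; the resulting zero-length branch triggers a
#' warning.  Calibrated nodes are fixed points: running bladj twice changes
#' nothing.
#'
#' @param tree a `phylo`; node labels identify calibrated internal nodes.
#' @param calib a `calibration_set`; must fix the root's age.
#' @return the tree with `edge.length` set to age differences and a
#'   `node.age` component holding every node's age.
#' @examples
#' tr <- read_newick(text = "(((A,B)n1,C)n2,D)root;")
#' out <- bladj(tr, calibration_set(c(root = 12)))
#' out$node.age   # n2 = 8, n1 = 4, tips 0
#' @export
bladj <- function(tree, calib) {
  validate_tree(tree)
  stopifnot(inherits(calib, "calibration_set"))
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  labs <- tree_node_labels(tree)
  par <- tree_parents(tree)
  root <- root_node(tree)

  age <- rep(NA_real_, n)
  fixed <- rep(FALSE, n)
  unknown <- setdiff(names(calib$ages), labs[!is.na(labs)])
  if (length(unknown)) {
    warning("calibration labels not in tree: ", paste(unknown, collapse = ", "))
  }
  for (lab in names(calib$ages)) {
    v <- which(!is.na(labs) & labs == lab)
    if (!length(v)) next
    if (length(v) > 1) stop("calibration label \"", lab, "\" matches several nodes")
    age[v] <- calib$ages[[lab]]; fixed[v] <- TRUE
  }
  tips <- seq_len(ntip)
  age[tips][!fixed[tips]] <- calib$default_tip_age
  fixed[tips] <- TRUE
  if (!fixed[root]) {
    stop("calibration error: the root age is not fixed (label the root and calibrate it)")
  }

  # consistency: no fixed descendant older than its nearest fixed ancestor
  for (v in which(fixed)) {
    if (v == root) next
    u <- par[v]
    while (u != 0L && !fixed[u]) u <- par[u]
    if (u != 0L && age[v] > age[u] + 1e-12) {
      stop("calibration error: fixed age of \"",
           if (is.na(labs[v])) paste("node", v) else labs[v], "\" (", age[v],
           ") exceeds fixed ancestor \"",
           if (is.na(labs[u])) paste("node", u) else labs[u], "\" (", age[u], ")")
    }
  }

  kids <- vector("list", n)
  for (k in seq_len(nrow(tree$edge))) {
    kids[[tree$edge[k, 1]]] <- c(kids[[tree$edge[k, 1]]], tree$edge[k, 2])
  }
  orig_fixed <- fixed
  collided <- FALSE
  pre <- unique(tree$edge[, 1])           # internal nodes, root first (preorder)
  for (v in pre) {
    if (orig_fixed[v]) next
    a_top <- age[par[v]]
    # nearest originally-fixed descendant on every chain below v
    best_k <- -1L; a_bot <- NA_real_
    stack_v <- kids[[v]]; stack_d <- rep(1L, length(stack_v))
    while (length(stack_v)) {
      w <- stack_v[length(stack_v)]; d <- stack_d[length(stack_d)]
      stack_v <- stack_v[-length(stack_v)]; stack_d <- stack_d[-length(stack_d)]
      if (orig_fixed[w]) {
        if (d > best_k || (d == best_k && age[w] > a_bot)) { best_k <- d; a_bot <- age[w] }
      } else {
        stack_v <- c(stack_v, kids[[w]])
        stack_d <- c(stack_d, rep(d + 1L, length(kids[[w]])))
      }
    }
    a <- a_top - (a_top - a_bot) / (best_k + 1)
    # monotonicity guard against fixed descendants on other chains
    max_desc <- max_fixed_desc_age(v, kids, orig_fixed, age)
    if (a < max_desc) { a <- max_desc; collided <- TRUE }
    if (a > a_top) { a <- a_top; collided <- TRUE }
    age[v] <- a
  }
  if (collided) {
    warning("age interpolation collided with a fixed age; zero-length branch(es) produced")
  }

  el <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  el[abs(el) < 1e-12] <- 0
  tree$edge.length <- el
  tree$node.age <- age
  tree
}

max_fixed_desc_age <- function(v, kids, fixed, age) {
  best <- 0
  stack <- kids[[v]]
  while (length(stack)) {
    w <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (fixed[w]) best <- max(best, age[w])
    else stack <- c(stack, kids[[w]])
  }
  best
}
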