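# Expression-tree genotype for symbolic regression.
#
# A tree node is a plain list:
#   list(op = "var",   name = <chr>)
#   list(op = "const", value = <num>)
#   list(op = "neg"|"sin"|"pexp", a = <node>)
#   list(op = "add"|"mul",        a = <node>, b = <node>)
# Complexity is the node count. Constant slots are ordered by pre-order
# traversal, which fixes the layout of the constants vector used by the
# optimizer and the prefix serialization.

.gp_unary <- c("neg", "sin", "pexp")
.gp_binary <- c("add", "mul")

#' Overflow-protected exponential
#'
#' `exp()` with its argument clamped to `[-50, 50]`, the protected primitive
#' used in evolved expressions so that no genotype can produce an overflow.
#'
#' @param x Numeric vector.
#' @return `exp(pmin(pmax(x, -50), 50))`.
#' @export
exp_protected <- function(x) exp(pmin(pmax(x, -50), 50))

gp_var <- function(name) list(op = "var", name = name)
gp_const <- function(value) list(op = "const", value = value)
gp_node <- function(op, a, b = NULL) {
  if (op %in% .gp_unary) list(op = op, a = a)
  else if (op %in% .gp_binary) list(op = op, a = a, b = b)
  else stop("unknown operator: ", op)
}

#' Tree utilities
#'
#' `tree_size()` counts nodes (the complexity measure), `tree_variables()`
#' lists the distinct variable names a tree references, `n_constants()`
#' counts constant slots, and `get_constants()` / `set_constants()` read and
#' write the constant values in pre-order.
#'
#' @param tree An expression tree.
#' @param values Numeric vector of constant values, pre-order.
#' @return Respectively: integer; character vector; integer; numeric vector;
#'   the modified tree.
#' @export
tree_size <- function(tree) {
  switch(tree$op,
         var = 1L, const = 1L,
         add = , mul = 1L + tree_size(tree$a) + tree_size(tree$b),
         1L + tree_size(tree$a))
}

#' @rdname tree_size
#' @export
tree_variables <- function(tree) {
  switch(tree$op,
         var = tree$name, const = character(),
         add = , mul = unique(c(tree_variables(tree$a),
                                tree_variables(tree$b))),
         tree_variables(tree$a))
}

#' @rdname tree_size
#' @export
get_constants <- function(tree) {
  switch(tree$op,
         var = numeric(), const = tree$value,
         add = , mul = c(get_constants(tree$a), get_constants(tree$b)),
         get_constants(tree$a))
}

#' @rdname tree_size
#' @export
n_constants <- function(tree) length(get_constants(tree))

#' @rdname tree_size
#' @export
set_constants <- function(tree, values) {
  stopifnot(length(values) == n_constants(tree))
  walk <- function(node, offset) {
    if (node$op == "const") {
      node$value <- values[offset + 1L]
      return(list(node = node, used = 1L))
    }
    if (node$op == "var") return(list(node = node, used = 0L))
    ra <- walk(node$a, offset)
    node$a <- ra$node
    used <- ra$used
    if (node$op %in% .gp_binary) {
      rb <- walk(node$b, offset + used)
      node$b <- rb$node
      used <- used + rb$used
    }
    list(node = node, used = used)
  }
  walk(tree, 0L)$node
}

#' Evaluate an expression tree on a table
#'
#' Pointwise (vectorized) recursive evaluation of a tree over the columns of
#' a data frame. The protected exponential clamps its argument to
#' `[-50, 50]`. If `constants` is supplied it overrides the constant values
#' embedded in the tree (pre-order layout).
#'
#' A second, independent evaluation route exists via [tree_to_call()] plus
#' base R `eval()`; the two are held to agreement at 1e-10 in the test suite.
#'
#' @param tree An expression tree.
#' @param data Data frame (or list/environment) whose columns cover
#'   `tree_variables(tree)`.
#' @param constants Optional replacement constants vector.
#' @return Numeric prediction vector.
#' @export
eval_tree <- function(tree, data, constants = NULL) {
  if (!is.null(constants)) tree <- set_constants(tree, constants)
  rec <- function(node) {
    switch(node$op,
           var = {
             v <- data[[node$name]]
             if (is.null(v)) stop("unknown variable reference: ", node$name)
             v
           },
           const = node$value,
           add = rec(node$a) + rec(node$b),
           mul = rec(node$a) * rec(node$b),
           neg = -rec(node$a),
           sin = sin(rec(node$a)),
           pexp = exp_protected(rec(node$a)),
           stop("unknown operator: ", node$op))
  }
  rec(tree)
}

#' Compile a tree to an R call
#'
#' Builds the R language object equivalent to the tree (with constants
#' inlined as literals), so that base R's own evaluator can serve both as a
#' fast execution path and as an independent cross-check of [eval_tree()].
#'
#' @param tree An expression tree.
#' @return A `call` (or name/numeric for leaf trees); evaluate it with
#'   [eval_tree_call()].
#' @export
tree_to_call <- function(tree) {
  switch(tree$op,
         var = as.name(tree$name),
         const = tree$value,
         add = call("+", tree_to_call(tree$a), tree_to_call(tree$b)),
         mul = call("*", tree_to_call(tree$a), tree_to_call(tree$b)),
         neg = call("-", tree_to_call(tree$a)),
         sin = call("sin", tree_to_call(tree$a)),
         pexp = call("exp_protected", tree_to_call(tree$a)),
         stop("unknown operator: ", tree$op))
}

#' @rdname tree_to_call
#' @param cl A call from [tree_to_call()].
#' @param data Data frame supplying the variable columns.
#' @export
eval_tree_call <- function(cl, data) {
  eval(cl, data, enclos = environment(exp_protected))
}

#' Prefix-notation serialization
#'
#' Expression trees round-trip through a whitespace-separated prefix grammar:
#' `(op arg ...)` for operators, a bare name for a variable, a numeric
#' literal for a constant. Example: `(add (sin X11) (mul 2 X8))`.
#'
#' @param tree An expression tree.
#' @return `tree_to_prefix()`: a single string; `prefix_to_tree()`: a tree.
#' @export
tree_to_prefix <- function(tree) {
  switch(tree$op,
         var = tree$name,
         const = format(tree$value, digits = 17, scientific = TRUE,
                        trim = TRUE),
         add = , mul = paste0("(", tree$op, " ", tree_to_prefix(tree$a), " ",
                              tree_to_prefix(tree$b), ")"),
         paste0("(", tree$op, " ", tree_to_prefix(tree$a), ")"))
}

#' @rdname tree_to_prefix
#' @param text Prefix-notation string.
#' @export
prefix_to_tree <- function(text) {
  tokens <- strsplit(gsub("([()])", " \\1 ", text), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  pos <- 0L
  peek <- function() tokens[pos + 1L]
  take <- function() {
    pos <<- pos + 1L
    tokens[pos]
  }
  parse_node <- function() {
    tok <- take()
    if (tok == "(") {
      op <- take()
      if (op %in% .gp_binary) {
        a <- parse_node(); b <- parse_node()
        node <- gp_node(op, a, b)
      } else if (op %in% .gp_unary) {
        node <- gp_node(op, parse_node())
      } else stop("unknown operator in prefix string: ", op)
      if (take() != ")") stop("malformed prefix string: expected ')'")
      node
    } else if (grepl("^[+-]?([0-9]|\\.[0-9])", tok)) {
      gp_const(as.numeric(tok))
    } else {
      gp_var(tok)
    }
  }
  node <- parse_node()
  if (pos != length(tokens)) stop("trailing tokens in prefix string")
  node
}
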