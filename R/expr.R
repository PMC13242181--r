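# Closed expression language over table columns. Expressions are small
# ASTs built from col() references, literals and overloaded operators;
# they are type-checked against a table schema and evaluated vectorized
# on row chunks. Missing values follow strict propagation: any unary or
# binary operation on missing is missing; only isMissing() inspects
# missingness. (Stricter than R's `FALSE & NA`, and enforced identically
# in memory and disk mode because both modes run this evaluator.)

#' Reference a table column in an expression
#'
#' @param name Column name.
#' @return A [TableExpr-class] node.
#' @examples
#' e <- col("mz") > 100 & !isMissing(col("name"))
#' @export
col <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  new("TableExpr", node = list(kind = "col", name = name))
}

#' @describeIn col Wrap a literal value explicitly (numeric, character or
#'   logical scalar). Bare literals in operator expressions are wrapped
#'   automatically.
#' @param x A scalar literal.
#' @export
lit <- function(x) {
  stopifnot(length(x) == 1L, is.numeric(x) || is.character(x) ||
              is.logical(x))
  new("TableExpr", node = list(kind = "lit", value = x))
}

#' @describeIn col Missing-value test; the only construct that sees
#'   missingness.
#' @param e A [TableExpr-class].
#' @export
isMissing <- function(e) {
  e <- .asExpr(e)
  new("TableExpr", node = list(kind = "ismissing", arg = e@node))
}

.asExpr <- function(x) {
  if (is(x, "TableExpr")) return(x)
  lit(x)
}

.BINOPS <- c("+", "-", "*", "/", "^", "%%", "%/%",
             "==", "!=", "<", "<=", ">", ">=", "&", "|")

.exprBinary <- function(op, e1, e2) {
  new("TableExpr", node = list(kind = "binop", op = op,
                               left = .asExpr(e1)@node,
                               right = .asExpr(e2)@node))
}

setMethod("Ops", signature("TableExpr", "TableExpr"), function(e1, e2) {
  if (!.Generic %in% .BINOPS) stop("operator not in expression language: ",
                                   .Generic)
  .exprBinary(.Generic, e1, e2)
})

setMethod("Ops", signature("TableExpr", "ANY"), function(e1, e2) {
  if (missing(e2))  # unary + / -
    return(new("TableExpr", node = list(kind = "unop", op = .Generic,
                                        arg = e1@node)))
  if (!.Generic %in% .BINOPS) stop("operator not in expression language: ",
                                   .Generic)
  .exprBinary(.Generic, e1, e2)
})

setMethod("Ops", signature("ANY", "TableExpr"), function(e1, e2) {
  if (!.Generic %in% .BINOPS) stop("operator not in expression language: ",
                                   .Generic)
  .exprBinary(.Generic, e1, e2)
})

#' @export
setMethod("!", "TableExpr", function(x)
  new("TableExpr", node = list(kind = "unop", op = "!", arg = x@node)))

setMethod("show", "TableExpr", function(object) {
  cat("TableExpr:", .exprDeparse(object@node), "\n")
})

.exprDeparse <- function(node) {
  switch(node$kind,
    col = node$name,
    lit = deparse(node$value),
    ismissing = paste0("isMissing(", .exprDeparse(node$arg), ")"),
    unop = paste0(node$op, .exprDeparse(node$arg)),
    binop = paste0("(", .exprDeparse(node$left), " ", node$op, " ",
                   .exprDeparse(node$right), ")"))
}

# R storage class -> column type name
.rTypeOf <- function(v) {
  if (is.integer(v)) "integer"
  else if (is.double(v)) "real"
  else if (is.character(v)) "text"
  else if (is.logical(v)) "boolean"
  else stop("unsupported value class: ", class(v)[1])
}

# static type of an expression against a schema; errors on unknown columns
# and operator/type mismatches
.exprType <- function(node, colNames, colTypes) {
  tOf <- function(n) .exprType(n, colNames, colTypes)
  switch(node$kind,
    col = {
      i <- match(node$name, colNames)
      if (is.na(i)) stop("unknown column in expression: ", node$name,
                         call. = FALSE)
      colTypes[i]
    },
    lit = .rTypeOf(node$value),
    ismissing = "boolean",
    unop = {
      t1 <- tOf(node$arg)
      if (node$op == "!") {
        if (t1 != "boolean") stop("'!' needs a boolean operand")
        "boolean"
      } else {
        if (!t1 %in% c("integer", "real"))
          stop("unary '", node$op, "' needs a numeric operand")
        t1
      }
    },
    binop = {
      t1 <- tOf(node$left); t2 <- tOf(node$right)
      num <- c("integer", "real")
      if (node$op %in% c("+", "-", "*", "/", "^", "%%", "%/%")) {
        if (!(t1 %in% num && t2 %in% num))
          stop("arithmetic '", node$op, "' needs numeric operands, got ",
               t1, " and ", t2)
        if (node$op %in% c("/", "^")) "real"
        else if (t1 == "real" || t2 == "real") "real" else "integer"
      } else if (node$op %in% c("==", "!=", "<", "<=", ">", ">=")) {
        comparable <- (t1 %in% num && t2 %in% num) || t1 == t2
        if (!comparable)
          stop("cannot compare ", t1, " with ", t2)
        "boolean"
      } else {  # & |
        if (t1 != "boolean" || t2 != "boolean")
          stop("'", node$op, "' needs boolean operands")
        "boolean"
      }
    })
}

# evaluate on a chunk (named list of column vectors, all length n);
# returns a vector of length n with strict missing propagation
.exprEval <- function(node, chunk, n) {
  ev <- function(x) .exprEval(x, chunk, n)
  switch(node$kind,
    col = chunk[[node$name]],
    lit = rep(node$value, n),
    ismissing = is.na(ev(node$arg)),
    unop = {
      v <- ev(node$arg)
      switch(node$op, "!" = !v, "-" = -v, "+" = v)
    },
    binop = {
      l <- ev(node$left); r <- ev(node$right)
      v <- switch(node$op,
        "+" = l + r, "-" = l - r, "*" = l * r, "/" = l / r,
        "^" = l ^ r, "%%" = l %% r, "%/%" = l %/% r,
        "==" = l == r, "!=" = l != r, "<" = l < r, "<=" = l <= r,
        ">" = l > r, ">=" = l >= r,
        "&" = l & r, "|" = l | r)
      if (node$op %in% c("&", "|"))
        v[is.na(l) | is.na(r)] <- NA   # strict, unlike R's Kleene cases
      v
    })
}
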