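# Kinetic-law expressions are stored as plain arithmetic strings
# (+, -, *, /, ^, function calls, identifiers, numbers) and serialized to
# SBML's MathML subset on export; import inverts the mapping. Expressions
# are normalized through the R parser so that a round trip is exact.

.mathml_ops <- c("+" = "plus", "-" = "minus", "*" = "times",
                 "/" = "divide", "^" = "power")

# parse + validate an expression string; returns the normalized string
normalize_math <- function(expr, known = NULL) {
  lang <- tryCatch(str2lang(expr),
                   error = function(e) stop_input(sprintf("cannot parse expression '%s'", expr)))
  .check_math(lang)
  if (!is.null(known)) {
    used <- all.vars(lang)
    bad <- setdiff(used, known)
    if (length(bad))
      stop_input(sprintf("unknown identifier%s in expression '%s': %s",
                         if (length(bad) > 1) "s" else "", expr,
                         paste(bad, collapse = ", ")))
  }
  paste(deparse(lang), collapse = " ")
}

.check_math <- function(e) {
  if (is.numeric(e) || is.name(e)) return(invisible(TRUE))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(.check_math(e[[2]]))
    for (i in seq_along(e)[-1]) .check_math(e[[i]])
    return(invisible(TRUE))
  }
  stop_input(sprintf("unsupported construct in expression: %s", deparse(e)))
}

# R language object -> MathML element string (no <math> wrapper)
.lang_to_mathml <- function(e) {
  if (is.numeric(e)) {
    if (is.finite(e) && e == round(e) && abs(e) < 2^31)
      return(sprintf("<cn type=\"integer\">%d</cn>", as.integer(e)))
    return(sprintf("<cn>%s</cn>", format(e, digits = 17)))
  }
  if (is.name(e)) return(sprintf("<ci>%s</ci>", as.character(e)))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(.lang_to_mathml(e[[2]]))
    args <- vapply(as.list(e)[-1], .lang_to_mathml, character(1))
    head <- if (op %in% names(.mathml_ops))
      sprintf("<%s/>", .mathml_ops[[op]]) else sprintf("<ci>%s</ci>", op)
    return(paste0("<apply>", head, paste(args, collapse = ""), "</apply>"))
  }
  stop_input(sprintf("unsupported construct in expression: %s", deparse(e)))
}

math_to_mathml <- function(expr) {
  paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
         .lang_to_mathml(str2lang(expr)), "</math>")
}

# xml2 node (child of <math>) -> R language object
.mathml_to_lang <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "cn") return(as.numeric(xml2::xml_text(node)))
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    headnm <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], .mathml_to_lang)
    inv <- names(.mathml_ops)[match(headnm, .mathml_ops)]
    op <- if (!is.na(inv)) inv else trimws(xml2::xml_text(kids[[1]]))
    return(as.call(c(as.name(op), args)))
  }
  stop_input(sprintf("unsupported MathML element '%s'", nm))
}

mathml_to_math <- function(math_node) {
  kids <- xml2::xml_children(math_node)
  if (length(kids) != 1L) stop_input("malformed MathML: expected one root expression")
  paste(deparse(.mathml_to_lang(kids[[1]])), collapse = " ")
}
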