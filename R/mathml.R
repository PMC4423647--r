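# MathML (content markup) to infix-string rendering. Only the textual
# form is preserved downstream -- the converted RDF carries equations as
# strings, not as semantic structures -- so the renderer aims for a
# readable, deterministic formula, not for evaluable semantics.

.MATHML_INFIX <- c(
  plus = "+", minus = "-", times = "*", divide = "/",
  eq = "==", neq = "!=", lt = "<", leq = "<=", gt = ">", geq = ">=",
  and = "&&", or = "||"
)

#' Render content MathML to an infix formula string
#'
#' Handles the operators that occur in kinetic laws and rules of the
#' literature corpus: n-ary arithmetic, powers and roots, elementary
#' functions, relational operators, piecewise expressions and lambda
#' abstractions. Anything unrenderable falls back to the raw MathML
#' text, with a log note, so no equation is ever silently dropped.
#'
#' @param math an `xml2` node for the `math` element or a string of
#'   MathML.
#' @return Character scalar.
#' @examples
#' mathml_to_infix(paste0(
#'   '<math xmlns="http://www.w3.org/1998/Math/MathML">',
#'   '<apply><times/><ci>k</ci><ci>S1</ci></apply></math>'))
#' @export
mathml_to_infix <- function(math) {
  raw <- if (is.character(math)) math else as.character(math)
  node <- tryCatch({
    if (is.character(math)) xml2::xml_root(xml2::read_xml(math)) else math
  }, error = function(e) NULL)
  if (is.null(node)) {
    log_note("unrenderable MathML kept as raw text")
    return(flatten_text(raw) %||% raw)
  }
  tryCatch(
    render_math_node(node),
    error = function(e) {
      log_note("unrenderable MathML kept as raw text: ", conditionMessage(e))
      flatten_text(raw) %||% raw
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

element_children <- function(node) {
  kids <- xml2::xml_children(node)
  as.list(kids)
}

render_math_node <- function(node) {
  nm <- xml2::xml_name(node)
  kids <- element_children(node)
  switch(nm,
    math = {
      if (!length(kids)) return("")
      paste(vapply(kids, render_math_node, character(1)), collapse = "; ")
    },
    apply = render_apply(kids),
    ci = trimws(xml2::xml_text(node)),
    cn = render_cn(node),
    csymbol = trimws(xml2::xml_text(node)),
    true = "true",
    false = "false",
    pi = "pi",
    exponentiale = "e",
    infinity = "INF",
    notanumber = "NaN",
    piecewise = render_piecewise(kids),
    lambda = render_lambda(kids),
    stop("unsupported MathML element <", nm, ">")
  )
}

render_apply <- function(kids) {
  if (!length(kids)) stop("empty <apply>")
  op <- kids[[1]]
  op_name <- xml2::xml_name(op)
  args <- vapply(kids[-1], render_math_node, character(1))

  if (op_name %in% names(.MATHML_INFIX)) {
    sym <- .MATHML_INFIX[[op_name]]
    if (op_name == "minus" && length(args) == 1) return(paste0("(-", args, ")"))
    return(paste0("(", paste(args, collapse = paste0(" ", sym, " ")), ")"))
  }
  switch(op_name,
    power = paste0("(", args[1], "^", args[2], ")"),
    root = {
      degree_node <- Filter(function(k) xml2::xml_name(k) == "degree", kids[-1])
      vals <- vapply(
        Filter(function(k) xml2::xml_name(k) != "degree", kids[-1]),
        render_math_node, character(1))
      if (length(degree_node)) {
        d <- render_math_node(element_children(degree_node[[1]])[[1]])
        paste0("root(", d, ", ", vals[1], ")")
      } else {
        paste0("sqrt(", vals[1], ")")
      }
    },
    not = paste0("!(", args[1], ")"),
    ci = ,
    csymbol = paste0(trimws(xml2::xml_text(op)), "(", paste(args, collapse = ", "), ")"),
    # elementary functions: exp, ln, log, sin, cos, tan, abs, floor, ...
    paste0(op_name, "(", paste(args, collapse = ", "), ")")
  )
}

render_cn <- function(node) {
  type <- xml2::xml_attr(node, "type")
  text_parts <- trimws(strsplit(xml2::xml_text(node), "[[:space:]]+")[[1]])
  text_parts <- text_parts[nzchar(text_parts)]
  has_sep <- length(xml2::xml_find_all(node, "./*[local-name()='sep']")) > 0
  if (has_sep && length(text_parts) >= 2) {
    if (!is.na(type) && type == "rational") {
      return(paste0("(", text_parts[1], "/", text_parts[2], ")"))
    }
    return(paste0(text_parts[1], "e", text_parts[2]))
  }
  paste(text_parts, collapse = "")
}

render_piecewise <- function(kids) {
  parts <- character()
  for (k in kids) {
    knm <- xml2::xml_name(k)
    sub <- element_children(k)
    if (knm == "piece" && length(sub) >= 2) {
      parts <- c(parts, paste0(render_math_node(sub[[1]]), " if ",
        render_math_node(sub[[2]])))
    } else if (knm == "otherwise" && length(sub) >= 1) {
      parts <- c(parts, paste0(render_math_node(sub[[1]]), " otherwise"))
    }
  }
  paste0("piecewise(", paste(parts, collapse = "; "), ")")
}

render_lambda <- function(kids) {
  bvars <- character()
  body <- ""
  for (k in kids) {
    if (xml2::xml_name(k) == "bvar") {
      bvars <- c(bvars, render_math_node(element_children(k)[[1]]))
    } else {
      body <- render_math_node(k)
    }
  }
  paste0("lambda(", paste(bvars, collapse = ", "), ": ", body, ")")
}
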