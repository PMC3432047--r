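# Plain-text reaction-list format.
#
# One reaction per line:
#   id : 1.2 metA + metB --> 0.5 metC + metD      (irreversible, bounds [0, Inf))
#   id : metA <==> metB                           (reversible, bounds (-Inf, Inf))
# Either side may be empty (boundary reactions). Directive lines:
#   #gpr id : (geneA and geneB) or geneC
#   #subsystem id : free text
#   #confidence id : 1..4
#   #bounds id : <lb> <ub>          (numbers, or -inf/inf)
#   #objective id
#   #formula met : C6H12O6
#   #carbon met : 4                 (explicit count when no formula applies)
#   #name met : free text
# Comment lines start with "//" or "%". Metabolite ids ending in "_e" are
# external; all others cytosolic. Reactions touching exactly one metabolite
# are flagged as exchanges.

parse_side <- function(txt, id, lineno) {
  txt <- trimws(txt)
  if (!nzchar(txt)) return(numeric(0))
  terms <- strsplit(txt, "\\s*\\+\\s*")[[1]]
  coef <- numeric(length(terms))
  mets <- character(length(terms))
  for (k in seq_along(terms)) {
    parts <- strsplit(trimws(terms[k]), "\\s+")[[1]]
    if (length(parts) == 1L) {
      coef[k] <- 1; mets[k] <- parts
    } else if (length(parts) == 2L) {
      v <- suppressWarnings(as.numeric(parts[1]))
      if (is.na(v)) stop("line ", lineno, " (", id,
                         "): malformed stoichiometric coefficient '", parts[1], "'")
      coef[k] <- v; mets[k] <- parts[2]
    } else {
      stop("line ", lineno, " (", id, "): malformed term '", terms[k], "'")
    }
    if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", mets[k]))
      stop("line ", lineno, " (", id, "): invalid metabolite id '", mets[k], "'")
  }
  stats::setNames(coef, mets)
}

parse_bound_token <- function(x, lineno) {
  if (tolower(x) %in% c("inf", "+inf")) return(Inf)
  if (tolower(x) == "-inf") return(-Inf)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("line ", lineno, ": malformed bound '", x, "'")
  v
}

#' Parse a model from the plain-text reaction-list format
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return a `metabolic_model`. Round-trips with [write_model_text] up to
#'   whitespace.
#' @export
parse_model_text <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  rxns <- list()
  objective <- NA_character_
  met_info <- list()   # id -> list(formula, carbon, name)
  post <- list()       # directives applied after reactions exist
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "//") || startsWith(ln, "%")) next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#(\\w+)\\s+([^:]+?)\\s*(?::\\s*(.*))?$", ln))[[1]]
      if (length(m) < 3L) stop("line ", i, ": malformed directive: ", ln)
      dir <- m[2]; target <- m[3]; value <- if (length(m) >= 4) m[4] else ""
      switch(dir,
        gpr        = { post[[length(post) + 1L]] <- list("gpr", target, value, i) },
        subsystem  = { post[[length(post) + 1L]] <- list("subsystem", target, value, i) },
        confidence = { post[[length(post) + 1L]] <- list("confidence", target, value, i) },
        bounds     = { post[[length(post) + 1L]] <- list("bounds", target, value, i) },
        objective  = { objective <- target },
        formula    = { met_info[[target]] <- utils::modifyList(
                         met_info[[target]] %||% list(), list(formula = value)) },
        carbon     = { met_info[[target]] <- utils::modifyList(
                         met_info[[target]] %||% list(),
                         list(carbon = as.integer(value))) },
        name       = { met_info[[target]] <- utils::modifyList(
                         met_info[[target]] %||% list(), list(name = value)) },
        stop("line ", i, ": unknown directive '#", dir, "'")
      )
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("line ", i, ": cannot parse reaction line: ", ln)
    id <- m[2]; eq <- m[3]
    rev <- grepl("<==>", eq, fixed = TRUE)
    arrow <- if (rev) "<==>" else "-->"
    if (!grepl(arrow, eq, fixed = TRUE))
      stop("line ", i, " (", id, "): missing reaction arrow ('-->' or '<==>')")
    sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
    if (length(sides) == 1L) sides <- c(sides, "")
    lhs <- parse_side(sides[1], id, i)
    rhs <- parse_side(sides[2], id, i)
    st <- c(-lhs, rhs)
    if (anyDuplicated(names(st))) {      # metabolite on both sides: net coefficient
      uniq <- unique(names(st))
      st <- stats::setNames(vapply(uniq, function(u)
        sum(st[names(st) == u]), 0), uniq)
      st <- st[st != 0]
    }
    if (id %in% names(rxns)) stop("line ", i, ": duplicate reaction id '", id, "'")
    rxns[[id]] <- reaction(id, st,
                           lower_bound = if (rev) -Inf else 0,
                           upper_bound = Inf)
  }
  for (p in post) {
    id <- p[[2]]
    if (!(id %in% names(rxns)))
      stop("line ", p[[4]], ": directive for unknown reaction '", id, "'")
    r <- rxns[[id]]
    switch(p[[1]],
      gpr        = { r$gpr <- p[[3]] },
      subsystem  = { r$subsystem <- p[[3]] },
      confidence = {
        v <- as.integer(p[[3]])
        if (is.na(v) || !(v %in% 1:4))
          stop("line ", p[[4]], ": confidence must be 1..4")
        r$confidence <- v
      },
      bounds     = {
        b <- strsplit(trimws(p[[3]]), "\\s+")[[1]]
        if (length(b) != 2L) stop("line ", p[[4]], ": #bounds needs two values")
        r$lower_bound <- parse_bound_token(b[1], p[[4]])
        r$upper_bound <- parse_bound_token(b[2], p[[4]])
        if (r$lower_bound > r$upper_bound)
          stop("line ", p[[4]], ": lower bound exceeds upper bound")
      })
    rxns[[id]] <- r
  }
  met_ids <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry))))
  mets <- do.call(rbind, lapply(met_ids, function(mid) {
    info <- met_info[[mid]] %||% list()
    metabolite(mid,
               name = info$name %||% mid,
               formula = info$formula %||% NA_character_,
               carbon = info$carbon %||% NA_integer_)
  }))
  if (is.null(mets)) mets <- metabolite("x")[0, ]
  metabolic_model(mets, rxns, objective_id = objective)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_side <- function(st) {
  if (!length(st)) return("")
  paste(vapply(seq_along(st), function(k) {
    cf <- st[k]
    if (cf == 1) names(st)[k]
    else paste(format(cf, digits = 15, scientific = FALSE), names(st)[k])
  }, ""), collapse = " + ")
}

#' Write a model in the plain-text reaction-list format
#'
#' @param model a `metabolic_model`.
#' @param path output file; omit to return the lines invisibly.
#' @return character vector of lines, invisibly.
#' @export
write_model_text <- function(model, path = NULL) {
  out <- c("// metabolic model (reaction-list format)")
  for (r in model$reactions) {
    st <- r$stoichiometry
    lhs <- -st[st < 0]; rhs <- st[st > 0]
    rev <- is_reversible(r)
    out <- c(out, paste0(r$id, " : ", fmt_side(lhs),
                         if (rev) " <==> " else " --> ", fmt_side(rhs)))
    default_lb <- if (rev) -Inf else 0
    if (r$lower_bound != default_lb || r$upper_bound != Inf) {
      bt <- function(x) if (is.infinite(x)) ifelse(x > 0, "inf", "-inf")
                        else format(x, scientific = FALSE)
      out <- c(out, paste0("#bounds ", r$id, " : ", bt(r$lower_bound), " ",
                           bt(r$upper_bound)))
    }
    if (!is.na(r$gpr)) out <- c(out, paste0("#gpr ", r$id, " : ", r$gpr))
    if (!is.na(r$subsystem)) out <- c(out, paste0("#subsystem ", r$id, " : ", r$subsystem))
    if (!is.na(r$confidence)) out <- c(out, paste0("#confidence ", r$id, " : ", r$confidence))
  }
  mt <- model$metabolites
  for (i in seq_len(nrow(mt))) {
    if (!is.na(mt$formula[i]))
      out <- c(out, paste0("#formula ", mt$id[i], " : ", mt$formula[i]))
    else if (!is.na(mt$carbon[i]))
      out <- c(out, paste0("#carbon ", mt$id[i], " : ", mt$carbon[i]))
    if (mt$name[i] != mt$id[i])
      out <- c(out, paste0("#name ", mt$id[i], " : ", mt$name[i]))
  }
  if (!is.na(model$objective_id))
    out <- c(out, paste0("#objective ", model$objective_id))
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
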