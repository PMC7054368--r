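#' Construct a path model
#'
#' @param edges data.frame with columns \code{label}, \code{from}, \code{to}.
#' @param nodes optional character vector of node names; defaults to the
#'   nodes appearing in \code{edges} (sources first, in order of appearance).
#' @param exogenous character vector of exogenous node names; defaults to
#'   the nodes that are never an edge target.
#' @param fixedExogenous logical; fix exogenous variances to their sample
#'   values (fixed-x convention, default) instead of estimating them.
#' @return a validated [PathModel-class]
#' @examples
#' m <- pathModel(data.frame(label = c("b1", "b2"),
#'                           from  = c("x", "m"),
#'                           to    = c("m", "y")))
#' nodeNames(m)
#' @export
pathModel <- function(edges, nodes = NULL, exogenous = NULL,
                      fixedExogenous = TRUE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "from", "to") %in% names(edges)))
  edges$label <- as.character(edges$label)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(nodes))
    nodes <- unique(c(edges$from, edges$to))
  if (is.null(exogenous))
    exogenous <- setdiff(nodes, edges$to)
  new("PathModel", nodes = nodes, exogenous = exogenous,
      edges = edges[, c("label", "from", "to")],
      fixedExogenous = isTRUE(fixedExogenous))
}

#' @rdname PathModel-class
#' @export
setMethod("nodeNames", "PathModel", function(object) object@nodes)

#' @rdname PathModel-class
#' @export
setMethod("edgeTable", "PathModel", function(object) object@edges)

#' @rdname PathModel-class
#' @export
setMethod("exogenousNodes", "PathModel", function(object) object@exogenous)

#' @rdname modelDF
#' @export
setMethod("freeParamCount", "PathModel", function(object, ...) {
  nEndo <- length(setdiff(object@nodes, object@exogenous))
  nExoFree <- if (object@fixedExogenous) 0L else length(object@exogenous)
  nrow(object@edges) + nEndo + nExoFree
})

#' @rdname modelDF
#' @export
setMethod("modelDF", "PathModel", function(object, ...) {
  args <- list(...)
  p <- if (!is.null(args$p)) args$p else length(object@nodes)
  nFixedExo <- if (object@fixedExogenous) length(object@exogenous) else 0L
  as.integer(p * (p + 1) / 2 - freeParamCount(object) - nFixedExo)
})

setMethod("show", "PathModel", function(object) {
  endo <- setdiff(object@nodes, object@exogenous)
  cat(sprintf("PathModel: %d nodes (%d endogenous), %d edges, df = %d\n",
              length(object@nodes), length(endo), nrow(object@edges),
              modelDF(object)))
  if (length(object@exogenous))
    cat("  exogenous:", paste(object@exogenous, collapse = ", "),
        if (object@fixedExogenous) "(variance fixed to sample)\n" else
          "(variance free)\n")
  for (i in seq_len(nrow(object@edges)))
    cat(sprintf("  %s <- %s  [%s]\n", object@edges$to[i],
                object@edges$from[i], object@edges$label[i]))
  invisible(object)
})

# Edge sets of the built-in twin-cycle models. Node/edge symbols follow the
# conventional abbreviations (IS = OGIS insulin sensitivity, LF = liver fat,
# FI = fasting insulin secretion, FG = fasting glucose, PG = 2 h glucose,
# TG = triacylglycerol, PF = pancreatic fat, GS = glucose sensitivity,
# PA = physical activity); the node-symbol mapping is inferred from the
# outcome/parent structure of the reported edge tables.
.tcEdges <- function() {
  data.frame(
    label = c("is1", "lf1", "fi1", "fi2", "fg1", "fg2", "tg1", "tg2",
              "pf1", "gs1", "gs2", "pg1", "pg2"),
    from  = c("LF", "FI", "FG", "IS", "IS", "GS", "IS", "LF",
              "TG", "PF", "IS", "IS", "GS"),
    to    = c("IS", "LF", "FI", "FI", "FG", "FG", "TG", "TG",
              "PF", "GS", "GS", "PG", "PG"),
    stringsAsFactors = FALSE
  )
}

.tcpaEdges <- function() {
  pa <- data.frame(
    label = c("is2", "lf2", "fi3", "fg3", "tg3", "pf2", "gs3", "pg3"),
    from  = "PA",
    to    = c("IS", "LF", "FI", "FG", "TG", "PF", "GS", "PG"),
    stringsAsFactors = FALSE
  )
  rbind(.tcEdges(), pa)
}

#' Built-in twin-cycle path models
#'
#' \code{"TC"} is the twin-cycle model: 8 endogenous metabolic nodes and 13
#' edges, including the non-recursive feedback loop IS -> FI -> LF -> IS.
#' \code{"TC-PA"} adds physical activity (\code{PA}) as an exogenous node
#' with an edge into each of the 8 metabolic nodes (21 edges in total).
#'
#' @param name \code{"TC"} or \code{"TC-PA"} (case-insensitive; \code{"TCPA"}
#'   and \code{"tc_pa"} are accepted)
#' @param fixedExogenous passed to [pathModel()]
#' @return a [PathModel-class]
#' @examples
#' builtinModel("TC-PA")
#' @export
builtinModel <- function(name, fixedExogenous = TRUE) {
  key <- toupper(gsub("[^A-Za-z]", "", name))
  if (key == "TC") {
    m <- pathModel(.tcEdges(), fixedExogenous = fixedExogenous)
  } else if (key == "TCPA") {
    m <- pathModel(.tcpaEdges(), fixedExogenous = fixedExogenous)
  } else {
    stop("unknown model '", name, "'; available models: TC, TC-PA")
  }
  m
}

#' Parse a path-model specification
#'
#' Accepts either a character vector of declaration lines or the path to a
#' text/YAML/JSON file. The line format is one edge per line,
#' \code{"target <- source [label]"}, with optional \code{"node NAME"} or
#' \code{"node NAME exogenous"} declarations and \code{#} comments. YAML and
#' JSON documents carry \code{nodes} (names, or \code{{name, role}} records)
#' and \code{edges} (\code{{label, from, to}} records), plus an optional
#' \code{fixedExogenous} flag.
#'
#' @param spec character vector of lines, or a single file path
#' @param fixedExogenous default exogenous-variance convention when the
#'   document does not state one
#' @return a validated [PathModel-class]
#' @examples
#' parseModelSpec(c("m <- x [b1]", "y <- m [b2]"))
#' @export
parseModelSpec <- function(spec, fixedExogenous = TRUE) {
  if (length(spec) == 1L && file.exists(spec)) {
    ext <- tolower(sub(".*\\.", "", spec))
    if (ext %in% c("yaml", "yml"))
      return(.modelFromList(yaml::read_yaml(spec), fixedExogenous))
    if (ext == "json")
      return(.modelFromList(
        jsonlite::fromJSON(spec, simplifyDataFrame = FALSE), fixedExogenous))
    spec <- readLines(spec)
  }
  lines <- trimws(sub("#.*$", "", spec))
  lines <- lines[nzchar(lines)]
  nodes <- character(); exo <- character()
  lab <- from <- to <- character()
  for (ln in lines) {
    if (grepl("^node\\s+", ln)) {
      parts <- strsplit(ln, "\\s+")[[1]]
      nodes <- c(nodes, parts[2])
      if (length(parts) > 2 && tolower(parts[3]) == "exogenous")
        exo <- c(exo, parts[2])
      next
    }
    m <- regmatches(ln, regexec(
      "^(\\S+)\\s*<-\\s*(\\S+)\\s*\\[\\s*([^]]+?)\\s*\\]$", ln))[[1]]
    if (length(m) != 4)
      stop("cannot parse model line: '", ln,
           "' (expected \"target <- source [label]\")")
    to <- c(to, m[2]); from <- c(from, m[3]); lab <- c(lab, m[4])
  }
  if (!length(lab)) stop("model specification declares no edges")
  allNodes <- unique(c(nodes, from, to))
  if (!length(exo)) exo <- NULL
  pathModel(data.frame(label = lab, from = from, to = to,
                       stringsAsFactors = FALSE),
            nodes = allNodes, exogenous = exo,
            fixedExogenous = fixedExogenous)
}

.modelFromList <- function(x, fixedExogenous) {
  ed <- do.call(rbind, lapply(x$edges, function(e)
    data.frame(label = e$label, from = e$from, to = e$to,
               stringsAsFactors = FALSE)))
  nodes <- exo <- NULL
  if (!is.null(x$nodes)) {
    if (is.character(x$nodes)) {
      nodes <- x$nodes
    } else {
      nodes <- vapply(x$nodes, function(n) n$name, character(1))
      roles <- vapply(x$nodes, function(n)
        if (is.null(n$role)) "endogenous" else n$role, character(1))
      exo <- nodes[roles == "exogenous"]
      if (!length(exo)) exo <- NULL
    }
  }
  if (!is.null(x$fixedExogenous)) fixedExogenous <- isTRUE(x$fixedExogenous)
  pathModel(ed, nodes = nodes, exogenous = exo,
            fixedExogenous = fixedExogenous)
}

#' Serialise a path model to declaration lines
#'
#' Inverse of [parseModelSpec()]: \code{parseModelSpec(writeModelSpec(m))}
#' reproduces \code{m}.
#'
#' @param model a [PathModel-class]
#' @param file optional path; when given, lines are written there
#' @return character vector of lines, invisibly when \code{file} is given
#' @export
writeModelSpec <- function(model, file = NULL) {
  lines <- c(
    paste("node", model@nodes,
          ifelse(model@nodes %in% model@exogenous, "exogenous", "")),
    sprintf("%s <- %s [%s]", model@edges$to, model@edges$from,
            model@edges$label)
  )
  lines <- trimws(lines)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Export a path model as a Graphviz DOT digraph
#'
#' @param model a [PathModel-class]
#' @param file optional output path
#' @return the DOT source as a character scalar
#' @export
exportDOT <- function(model, file = NULL) {
  ed <- model@edges
  body <- c(
    sprintf("  %s [shape=box];", model@nodes),
    sprintf("  %s -> %s [label=\"%s\"];", ed$from, ed$to, ed$label)
  )
  dot <- paste(c("digraph pathmodel {", body, "}"), collapse = "\n")
  if (!is.null(file)) writeLines(dot, file)
  invisible(dot)
}

#' Enumerate simple directed paths between two nodes
#'
#' Depth-first enumeration of all simple (no repeated node) directed paths
#' from \code{source} to \code{sink} with at most \code{maxLength} nodes,
#' returned in deterministic lexicographic order of the node sequences.
#' Mediation pathways (e.g. PA -> IS -> FG) are exactly these paths.
#'
#' @param model a [PathModel-class]
#' @param source,sink node names, \code{source != sink}
#' @param maxLength maximum number of nodes on a path (>= 2);
#'   \code{Inf} for unbounded
#' @return list of paths; each a list with \code{nodes} (character vector)
#'   and \code{labels} (edge labels traversed)
#' @examples
#' m <- builtinModel("TC-PA")
#' paths <- enumerateDirectedPaths(m, "PA", "FG", maxLength = 5)
#' sapply(paths, function(p) paste(p$nodes, collapse = "->"))
#' @export
enumerateDirectedPaths <- function(model, source, sink, maxLength = Inf) {
  if (!source %in% model@nodes) stop("source node '", source, "' not in model")
  if (!sink %in% model@nodes) stop("sink node '", sink, "' not in model")
  if (source == sink) stop("source and sink must differ")
  if (maxLength < 2) stop("maxLength must be >= 2 nodes")
  ed <- model@edges
  out <- list()
  # children in sorted order => lexicographic output
  kids <- split(seq_len(nrow(ed)), ed$from)
  kids <- lapply(kids, function(i) i[order(ed$to[i])])
  walk <- function(nodePath, labPath) {
    tip <- nodePath[length(nodePath)]
    if (tip == sink) {
      out[[length(out) + 1L]] <<- list(nodes = nodePath, labels = labPath)
      return()
    }
    if (length(nodePath) >= maxLength) return()
    for (i in kids[[tip]]) {
      nxt <- ed$to[i]
      if (nxt %in% nodePath) next
      walk(c(nodePath, nxt), c(labPath, ed$label[i]))
    }
  }
  walk(source, character(0))
  out
}

# Edge lookup: label for a (from, to) pair, NA when absent.
.edgeLabel <- function(model, from, to) {
  hit <- model@edges$from == from & model@edges$to == to
  if (!any(hit)) NA_character_ else model@edges$label[hit]
}

#' Test whether a model contains a directed cycle
#' @param model a [PathModel-class]
#' @return logical
#' @export
hasCycle <- function(model) {
  ed <- model@edges
  colour <- setNames(rep(0L, length(model@nodes)), model@nodes)
  found <- FALSE
  visit <- function(v) {
    if (found) return()
    colour[v] <<- 1L
    for (w in ed$to[ed$from == v]) {
      if (colour[w] == 1L) { found <<- TRUE; return() }
      if (colour[w] == 0L) visit(w)
    }
    colour[v] <<- 2L
  }
  for (v in model@nodes) if (colour[v] == 0L) visit(v)
  found
}
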