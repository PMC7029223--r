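#' Read a signed weighted network
#'
#' Reads a network from GraphML, Cytoscape JSON (`.cyjs`), or a 3-column
#' weighted edge-list TSV (`source  target  weight`). Edge weights must be
#' present as a numeric attribute named `weight` (GraphML/cyjs) or as the
#' third column (TSV). Zero-weight edges are dropped with a warning; directed
#' input is collapsed to undirected, erroring if the two directions carry
#' conflicting weights.
#'
#' The TSV dialect is tab-separated; an optional header line is detected by a
#' non-numeric third field, and lines starting with `#` are comments.
#'
#' @param path file to read.
#' @param format one of `"auto"` (by extension), `"graphml"`, `"cyjs"`,
#'   `"edgelist"`.
#' @return a [signed_graph()].
#' @export
read_network <- function(path, format = c("auto", "graphml", "cyjs", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      graphml = "graphml", xml = "graphml",
      cyjs = "cyjs", json = "cyjs",
      tsv = "edgelist", txt = "edgelist", edgelist = "edgelist",
      stop("cannot infer format from extension: ", ext, call. = FALSE)
    )
  }
  switch(format,
    graphml = read_graphml(path),
    cyjs = read_cyjs(path),
    edgelist = read_edgelist(path)
  )
}

read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    return(signed_graph(data.frame(from = character(), to = character(),
                                   weight = numeric())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    stop("edge list rows must have 3 tab-separated fields (source, target, weight)",
         call. = FALSE)
  }
  third <- vapply(fields, `[[`, character(1), 3)
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(third[1])))) start <- 2L  # header
  if (start > length(fields)) {
    return(signed_graph(data.frame(from = character(), to = character(),
                                   weight = numeric())))
  }
  fields <- fields[start:length(fields)]
  w <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  if (any(is.na(w))) {
    stop("non-numeric weight in edge list body", call. = FALSE)
  }
  signed_graph(data.frame(
    from = vapply(fields, `[[`, character(1), 1),
    to = vapply(fields, `[[`, character(1), 2),
    weight = w
  ))
}

read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  key_for <- xml2::xml_attr(keys, "for")
  key_name <- xml2::xml_attr(keys, "attr.name")
  key_id <- xml2::xml_attr(keys, "id")
  wkey <- key_id[key_for == "edge" & key_name == "weight"]
  if (length(wkey) == 0) {
    stop("GraphML has no edge attribute named 'weight'", call. = FALSE)
  }
  wkey <- wkey[1]

  edges <- xml2::xml_find_all(doc, ".//edge")
  if (length(edges) > 0) {
    wdat <- vapply(edges, function(e) {
      d <- xml2::xml_find_first(e, sprintf("./data[@key='%s']", wkey))
      if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
    }, character(1))
    if (any(is.na(wdat))) {
      stop("GraphML edge missing its 'weight' data element", call. = FALSE)
    }
    edf <- data.frame(
      from = xml2::xml_attr(edges, "source"),
      to = xml2::xml_attr(edges, "target"),
      weight = as.numeric(wdat)
    )
  } else {
    edf <- data.frame(from = character(), to = character(), weight = numeric())
  }

  nodes <- xml2::xml_find_all(doc, ".//node")
  ids <- xml2::xml_attr(nodes, "id")
  # node attributes (cluster labels etc.) into node_attrs
  nkeys <- key_id[key_for == "node"]
  nnames <- key_name[key_for == "node"]
  attrs <- NULL
  if (length(nkeys) > 0 && length(nodes) > 0) {
    cols <- lapply(nkeys, function(k) {
      vapply(nodes, function(nd) {
        d <- xml2::xml_find_first(nd, sprintf("./data[@key='%s']", k))
        if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
      }, character(1))
    })
    names(cols) <- nnames
    keep <- vapply(cols, function(x) !all(is.na(x)), logical(1))
    if (any(keep)) {
      attrs <- tibble::as_tibble(c(list(node = ids), cols[keep]))
    }
  }
  signed_graph(edf, nodes = ids, node_attrs = attrs)
}

read_cyjs <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  el <- doc$elements
  if (is.null(el)) stop("not a Cytoscape JSON file: no 'elements'", call. = FALSE)
  nd <- el$nodes %||% list()
  ed <- el$edges %||% list()
  ids <- vapply(nd, function(x) as.character(x$data$id), character(1))
  if (length(ed) > 0) {
    w <- lapply(ed, function(x) x$data$weight)
    if (any(vapply(w, is.null, logical(1)))) {
      stop("Cytoscape JSON edge missing data.weight", call. = FALSE)
    }
    edf <- data.frame(
      from = vapply(ed, function(x) as.character(x$data$source), character(1)),
      to = vapply(ed, function(x) as.character(x$data$target), character(1)),
      weight = vapply(w, as.numeric, numeric(1))
    )
  } else {
    edf <- data.frame(from = character(), to = character(), weight = numeric())
  }
  attrs <- NULL
  if (length(nd) > 0) {
    extra <- unique(unlist(lapply(nd, function(x) setdiff(names(x$data), "id"))))
    if (length(extra) > 0) {
      cols <- lapply(extra, function(k) {
        vapply(nd, function(x) {
          v <- x$data[[k]]
          if (is.null(v)) NA_character_ else as.character(v)
        }, character(1))
      })
      names(cols) <- extra
      attrs <- tibble::as_tibble(c(list(node = ids), cols))
    }
  }
  signed_graph(edf, nodes = ids, node_attrs = attrs)
}

#' Write a signed network
#'
#' Writes the graph (with any node attributes present in `node_attrs`) as
#' GraphML, Cytoscape JSON, or a weighted edge-list TSV. The TSV carries edges
#' only; use [write_results()] for a node table.
#'
#' @param g a `signed_graph`.
#' @param path output file.
#' @param format `"auto"` (by extension), `"graphml"`, `"cyjs"`, `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path, format = c("auto", "graphml", "cyjs", "edgelist")) {
  stopifnot(is_signed_graph(g))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      graphml = "graphml", cyjs = "cyjs", json = "cyjs",
      tsv = "edgelist", txt = "edgelist",
      stop("cannot infer format from extension: ", ext, call. = FALSE)
    )
  }
  switch(format,
    graphml = write_graphml(g, path),
    cyjs = write_cyjs(g, path),
    edgelist = {
      df <- g$edges
      names(df) <- c("source", "target", "weight")
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)
    }
  )
  invisible(path)
}

node_attr_cols <- function(g) {
  cols <- setdiff(names(g$node_attrs), "node")
  cols[vapply(cols, function(cl) !all(is.na(g$node_attrs[[cl]])), logical(1))]
}

write_graphml <- function(g, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  cols <- node_attr_cols(g)
  xml2::xml_add_child(doc, "key", id = "w", "for" = "edge",
                      "attr.name" = "weight", "attr.type" = "double")
  for (i in seq_along(cols)) {
    type <- if (is.numeric(g$node_attrs[[cols[i]]])) "double" else "string"
    xml2::xml_add_child(doc, "key", id = paste0("n", i), "for" = "node",
                        "attr.name" = cols[i], "attr.type" = type)
  }
  graph <- xml2::xml_add_child(doc, "graph", edgedefault = "undirected")
  for (k in seq_along(g$nodes)) {
    nd <- xml2::xml_add_child(graph, "node", id = g$nodes[k])
    for (i in seq_along(cols)) {
      v <- g$node_attrs[[cols[i]]][match(g$nodes[k], g$node_attrs$node)]
      if (!is.na(v)) {
        d <- xml2::xml_add_child(nd, "data", key = paste0("n", i))
        xml2::xml_text(d) <- num_chr(v)
      }
    }
  }
  for (k in seq_len(n_edges(g))) {
    e <- xml2::xml_add_child(graph, "edge",
                             source = g$edges$from[k], target = g$edges$to[k])
    d <- xml2::xml_add_child(e, "data", key = "w")
    xml2::xml_text(d) <- num_chr(g$edges$weight[k])
  }
  xml2::write_xml(doc, path)
}

num_chr <- function(x) {
  if (is.numeric(x)) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  else as.character(x)
}

write_cyjs <- function(g, path) {
  cols <- node_attr_cols(g)
  nodes <- lapply(g$nodes, function(id) {
    dat <- list(id = id)
    for (cl in cols) {
      v <- g$node_attrs[[cl]][match(id, g$node_attrs$node)]
      if (!is.na(v)) dat[[cl]] <- v
    }
    list(data = dat)
  })
  edges <- lapply(seq_len(n_edges(g)), function(k) {
    list(data = list(source = g$edges$from[k], target = g$edges$to[k],
                     weight = g$edges$weight[k]))
  })
  jsonlite::write_json(
    list(elements = list(nodes = nodes, edges = edges)),
    path, auto_unbox = TRUE, digits = NA
  )
}

#' Write clustering results alongside the network
#'
#' Attaches the cluster assignment (and, when given, robustness confidence
#' intervals) to the graph as node attributes -- `cluster`, `assignment`
#' (`"strong"`/`"weak"`), `jaccard_lower`, `jaccard_upper` -- writes the
#' annotated network in the requested format, and writes a TSV twin
#' (`<path>_nodes.tsv`) listing node, cluster, weak flag and CI bounds.
#'
#' @param g a `signed_graph`.
#' @param assignment a cluster assignment as returned by [cluster_signed()]
#'   or [select_assignment()], or a data frame with columns `node`, `cluster`
#'   and optionally `weak`.
#' @param path output file for the network.
#' @param format passed to [write_network()]; `"tsv"` writes the edge list.
#' @param robustness optional robustness report from [cluster_robustness()].
#' @return `path`, invisibly.
#' @export
write_results <- function(g, assignment, path,
                          format = c("auto", "graphml", "cyjs", "edgelist"),
                          robustness = NULL) {
  stopifnot(is_signed_graph(g))
  memb <- as_membership_tbl(assignment)
  missing_nodes <- setdiff(memb$node, g$nodes)
  if (length(missing_nodes) > 0) {
    stop("assignment names node(s) absent from graph: ",
         paste(utils::head(missing_nodes, 5), collapse = ", "), call. = FALSE)
  }
  if (!all(g$nodes %in% memb$node)) {
    stop("assignment does not cover all graph nodes", call. = FALSE)
  }
  tbl <- dplyr::left_join(tibble::tibble(node = g$nodes), memb, by = "node")
  if (!"weak" %in% names(tbl)) tbl$weak <- FALSE
  tbl$assignment <- ifelse(tbl$weak, "weak", "strong")
  if (!is.null(robustness)) {
    pn <- robustness$node_robustness
    tbl <- dplyr::left_join(
      tbl, pn[, c("node", "jaccard_lower", "jaccard_upper")], by = "node")
  }
  g$node_attrs <- dplyr::left_join(
    g$node_attrs[, "node", drop = FALSE],
    tbl[, setdiff(names(tbl), "weak")], by = "node")
  write_network(g, path, format)
  twin <- paste0(tools::file_path_sans_ext(path), "_nodes.tsv")
  utils::write.table(tbl, twin, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# accept fitted objects or bare membership tables
as_membership_tbl <- function(assignment) {
  if (inherits(assignment, "signed_clusters")) {
    return(assignment$membership)
  }
  tbl <- tibble::as_tibble(assignment)
  stopifnot(all(c("node", "cluster") %in% names(tbl)))
  tbl$node <- as.character(tbl$node)
  tbl
}

`%||%` <- function(a, b) if (is.null(a)) b else a
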