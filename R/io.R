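#' @include simulate.R
#' @importFrom utils head tail read.delim write.table packageVersion
NULL

#' Read and write labeled TSV matrices
#'
#' Canonical tabular dialect: UTF-8, tab-delimited, header row, first
#' column of row labels.
#'
#' @param M matrix with dimnames.
#' @param path file path.
#' @return \code{readMatrixTSV} returns a numeric matrix.
#' @export
writeMatrixTSV <- function(M, path) {
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- as.character(df[[1]])
  storage.mode(M) <- "double"
  M
}

#' Read a module network from a file
#'
#' Accepted formats: a two-column tab-delimited edge list (header
#' optional), a square labeled adjacency matrix in TSV, or GraphML.
#' \code{format = "auto"} picks GraphML for .graphml/.xml extensions, an
#' adjacency matrix when the table is square with matching labels, and an
#' edge list otherwise.
#'
#' @param path file path.
#' @param format one of "auto", "edgelist", "adjacency", "graphml".
#' @param nodes optional character vector fixing the node set and order
#'   (required to represent isolated nodes in an edge list).
#' @return a \linkS4class{ModuleNetwork}.
#' @export
readNetwork <- function(path,
                        format = c("auto", "edgelist", "adjacency",
                                   "graphml"),
                        nodes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(graphml|xml)$", path, ignore.case = TRUE))
      "graphml"
    else {
      probe <- read.delim(path, header = FALSE, nrows = 5,
                          stringsAsFactors = FALSE)
      if (ncol(probe) > 3) "adjacency" else "edgelist"
    }
  }
  if (format == "graphml") {
    net <- moduleNetworkFromIgraph(
      igraph::read_graph(path, format = "graphml"))
    return(if (is.null(nodes)) net else .reorderNetwork(net, nodes))
  }
  if (format == "adjacency") {
    M <- readMatrixTSV(path)
    if (nrow(M) != ncol(M) ||
        !identical(rownames(M), colnames(M)))
      stop("adjacency TSV must be square with matching row/column labels")
    net <- moduleNetwork((M != 0) + 0, nodeLabels = rownames(M))
    return(if (is.null(nodes)) net else .reorderNetwork(net, nodes))
  }
  ## edge list
  el <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(el) < 2) stop("edge list must have two columns")
  el <- el[, 1:2]
  ## drop a header row if its entries never appear again as node labels
  if (nrow(el) > 1) {
    rest <- unique(c(el[-1, 1], el[-1, 2]))
    if (!any(el[1, ] %in% rest) && !is.null(nodes) &&
        !any(el[1, ] %in% nodes))
      el <- el[-1, , drop = FALSE]
    else if (all(tolower(unlist(el[1, ])) %in%
                   c("from", "to", "node1", "node2", "source", "target")))
      el <- el[-1, , drop = FALSE]
  }
  lab <- if (is.null(nodes)) sort(unique(c(el[[1]], el[[2]]))) else nodes
  miss <- setdiff(unique(c(el[[1]], el[[2]])), lab)
  if (length(miss))
    stop("edge list refers to nodes outside the given node set: ",
         paste(head(miss, 5), collapse = ", "))
  A <- matrix(0, length(lab), length(lab), dimnames = list(lab, lab))
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    if (a != b) { A[a, b] <- 1; A[b, a] <- 1 }
  }
  moduleNetwork(A, nodeLabels = lab)
}

.reorderNetwork <- function(net, nodes) {
  if (!setequal(nodes, net@nodeLabels))
    stop("node set of the network file does not match the requested nodes")
  moduleNetwork(net@adjacency[nodes, nodes], nodeLabels = nodes)
}

#' Load an analysis configuration
#'
#' A configuration is a named list (or a YAML/JSON file holding one) with
#' entries: \code{phenotype} (list: \code{path}, \code{trait}, optional
#' \code{covariates}), \code{modules} (list of two lists: \code{data},
#' optional \code{network}, optional \code{correlationThreshold} used to
#' build the network from the data correlations when no network file is
#' given, \code{kernel} in topology/connectivity/linear), and optional
#' \code{tests} ("all", or a subset of interaction/module1/module2),
#' \code{strategy} ("all" or "sequential"), \code{alpha},
#' \code{standardize}, \code{normalize}, \code{seed}, \code{outDir}.
#'
#' @param config list or path to a YAML or JSON file.
#' @return validated configuration list.
#' @export
analysisConfig <- function(config) {
  base <- NULL
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    base <- dirname(normalizePath(config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
    ## resolve input paths relative to the config file's directory
    rebase <- function(p) if (!is.null(p) && !file.exists(p) &&
                                file.exists(file.path(base, p)))
      file.path(base, p) else p
    config$phenotype$path <- rebase(config$phenotype$path)
    if (is.data.frame(config$modules))  # JSON simplification
      config$modules <- lapply(seq_len(nrow(config$modules)),
                               function(i) as.list(config$modules[i, ]))
    config$modules <- lapply(config$modules, function(m) {
      m$data <- rebase(m$data); m$network <- rebase(m$network); m
    })
  }
  stopifnot(is.list(config))
  defaults <- list(tests = "all", strategy = "all", alpha = 0.05,
                   standardize = TRUE, normalize = TRUE, seed = 1L,
                   outDir = ".")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$phenotype$path) || is.null(config$phenotype$trait))
    stop("config$phenotype needs 'path' and 'trait'")
  if (length(config$modules) != 2)
    stop("config$modules must describe exactly two modules")
  for (m in config$modules) {
    if (is.null(m$data)) stop("each module needs a 'data' path")
    kern <- if (is.null(m$kernel)) "topology" else m$kernel
    if (!(kern %in% c("topology", "connectivity", "linear")))
      stop("module kernel must be topology, connectivity or linear")
  }
  if (!(config$strategy %in% c("all", "sequential")))
    stop("strategy must be 'all' or 'sequential'")
  paths <- c(config$phenotype$path,
             vapply(config$modules, function(m) m$data, ""),
             unlist(lapply(config$modules, function(m) m$network)))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  config
}

.readSubjectTable <- function(path, what) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate subject IDs in ", what, " file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  M <- df[, -1, drop = FALSE]
  bad <- which(is.na(as.matrix(M)), arr.ind = TRUE)
  if (nrow(bad))
    stop("missing values in ", what, " file at ",
         paste(sprintf("(%s, %s)", ids[bad[, 1]],
                       colnames(M)[bad[, 2]])[seq_len(min(5, nrow(bad)))],
               collapse = "; "))
  rownames(M) <- ids
  M
}

#' Load a dataset described by an analysis configuration
#'
#' Reads the phenotype/covariate table and both module tables, inner-joins
#' on subject IDs in deterministic sorted order, aligns each module's
#' columns to its network's node labels (dropping and reporting unmatched
#' labels on either side), builds the requested kernels and assembles a
#' \linkS4class{KmModel}.
#'
#' @param config see \code{\link{analysisConfig}}.
#' @return list with \code{model}, \code{networks}, \code{kernels},
#'   \code{subjects}, \code{dropped} (per-module character vectors) and
#'   \code{nWarnings}.
#' @export
loadDataset <- function(config) {
  config <- analysisConfig(config)
  nWarn <- 0L
  note <- function(...) { nWarn <<- nWarn + 1L; warning(..., call. = FALSE) }

  pheno <- .readSubjectTable(config$phenotype$path, "phenotype")
  need <- c(config$phenotype$trait, config$phenotype$covariates)
  if (!all(need %in% colnames(pheno)))
    stop("phenotype file lacks column(s): ",
         paste(setdiff(need, colnames(pheno)), collapse = ", "))
  modTabs <- lapply(seq_along(config$modules), function(i)
    .readSubjectTable(config$modules[[i]]$data, paste0("module ", i)))

  subjects <- Reduce(intersect, c(list(rownames(pheno)),
                                  lapply(modTabs, rownames)))
  subjects <- sort(subjects)
  if (length(subjects) < 3)
    stop("fewer than 3 subject IDs shared across all input files")

  networks <- list(); kernels <- list(); dropped <- list()
  datas <- list()
  for (i in 1:2) {
    m <- config$modules[[i]]
    M <- as.matrix(modTabs[[i]][subjects, , drop = FALSE])
    storage.mode(M) <- "double"
    if (!is.null(m$network)) {
      net <- readNetwork(m$network)
    } else {
      thr <- if (is.null(m$correlationThreshold)) 0.5
             else m$correlationThreshold
      net <- adjacencyFromCorrelation(stats::cor(M), thr)
    }
    shared <- intersect(net@nodeLabels, colnames(M))
    if (length(shared) < 1) stop("module ", i,
                                 ": no shared node labels with network")
    dropCols <- setdiff(colnames(M), shared)
    dropNet <- setdiff(net@nodeLabels, shared)
    if (length(dropCols))
      note("module ", i, ": dropped data column(s) absent from network: ",
           paste(dropCols, collapse = ", "))
    if (length(dropNet))
      note("module ", i, ": dropped network node(s) absent from data: ",
           paste(dropNet, collapse = ", "))
    keep <- net@nodeLabels[net@nodeLabels %in% shared]  # network order
    net <- moduleNetwork(net@adjacency[keep, keep], nodeLabels = keep)
    X <- moduleData(M[, keep, drop = FALSE], nodeLabels = keep)
    tom <- topologicalOverlap(net)
    K <- switch(m$kernel %||% "topology",
      topology = topologyKernel(X, tom, standardize = config$standardize,
                                normalize = config$normalize),
      connectivity = connectivityKernel(X, connectivityWeights(tom),
                                        standardize = config$standardize,
                                        normalize = config$normalize),
      linear = linearKernel(X, standardize = config$standardize,
                            normalize = config$normalize))
    networks[[i]] <- net; kernels[[i]] <- K; datas[[i]] <- X
    dropped[[i]] <- c(dropCols, dropNet)
  }
  covar <- if (length(config$phenotype$covariates))
    as.matrix(pheno[subjects, config$phenotype$covariates, drop = FALSE])
  else NULL
  model <- kmModel(as.numeric(pheno[subjects, config$phenotype$trait]),
                   kernels[[1]], kernels[[2]], covariates = covar)
  list(model = model, networks = networks, kernels = kernels,
       data = datas, subjects = subjects, dropped = dropped,
       nWarnings = nWarn, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured analysis and write result files
#'
#' Executes the requested tests. With \code{strategy = "sequential"} the
#' interaction test runs first and the conditional tests run only when
#' the interaction p-value is >= alpha (the workflow used for real-data
#' module analysis: a significant interaction makes marginal conditional
#' tests moot). Writes \code{results.tsv}, \code{results.json} and
#' \code{log.txt} into \code{config$outDir}; the JSON embeds the seed,
#' package version and an MD5 hash of the effective configuration.
#'
#' @param config see \code{\link{analysisConfig}}.
#' @return the results data.frame, invisibly.
#' @export
runAnalysis <- function(config) {
  ds <- loadDataset(config)
  config <- ds$config
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  logLines <- c(sprintf("netKM %s | %s", packageVersion("netKM"),
                        format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                sprintf("subjects: %d", length(ds$subjects)),
                sprintf("load warnings: %d", ds$nWarnings))

  tests <- config$tests
  if (identical(tests, "all"))
    tests <- c("interaction", "module1", "module2")
  rows <- list(); skipped <- character()
  runOne <- function(tst) {
    res <- switch(tst,
      interaction = testInteraction(ds$model),
      module1 = testConditional(ds$model, 1),
      module2 = testConditional(ds$model, 2))
    logLines <<- c(logLines,
                   sprintf("%s: T = %.4f, p = %.4g%s", tst,
                           testStatistic(res), pValue(res),
                           if (res@fit@converged) "" else
                             " [fit not converged]"))
    resultAsData(res)
  }
  if (config$strategy == "sequential" && "interaction" %in% tests) {
    intRes <- runOne("interaction")
    rows[["interaction"]] <- intRes
    conds <- setdiff(tests, "interaction")
    if (intRes$p.value < config$alpha && length(conds)) {
      skipped <- conds
      logLines <- c(logLines, paste("not run (interaction significant):",
                                    paste(conds, collapse = ", ")))
    } else {
      for (tst in conds) rows[[tst]] <- runOne(tst)
    }
  } else {
    for (tst in tests) rows[[tst]] <- runOne(tst)
  }
  results <- do.call(rbind, rows)
  results$status <- "run"
  if (length(skipped))
    results <- rbind(results,
                     data.frame(test = skipped, statistic = NA, df = NA,
                                kappa = NA, p.value = NA, tau1 = NA,
                                tau2 = NA, tau12 = NA, sigma = NA,
                                converged = NA, n.iter = NA,
                                status = "not run (interaction significant)"))
  rownames(results) <- NULL

  cfgPath <- file.path(config$outDir, "config.json")
  jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  meta <- list(package = "netKM",
               version = as.character(packageVersion("netKM")),
               seed = config$seed, alpha = config$alpha,
               strategy = config$strategy,
               configHash = unname(tools::md5sum(cfgPath)),
               subjects = length(ds$subjects))
  write.table(results, file.path(config$outDir, "results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(meta = meta, results = results),
                       file.path(config$outDir, "results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(c(logLines, sprintf("config hash: %s", meta$configHash)),
             file.path(config$outDir, "log.txt"))
  invisible(results)
}
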