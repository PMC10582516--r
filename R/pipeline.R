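# Declarative pipeline runner: build -> annotate -> centrality/topology ->
# cluster -> consensus/bridgeness -> separation/ORA, driven by a config
# list or YAML file. Every output table carries a commented metadata header
# (tool version, seed, parameters) so runs are reproducible and auditable.

write_tsv_meta <- function(df, path, meta = list()) {
  meta <- c(list(tool = paste0("bionetkit ",
                               as.character(utils::packageVersion("bionetkit"))),
                 written = "deterministic"),
            meta)
  hdr <- vapply(names(meta), function(k) {
    sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " "))
  }, character(1L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the analysis pipeline from a config
#'
#' Executes the requested steps in pipeline order on a network loaded from
#' `config$input` (edge list, GML or GraphML). Supported steps:
#' `"centrality"`, `"powerlaw"`, `"entropy"`, `"cluster"`, `"summary"`,
#' `"consensus"`, `"bridgeness"`, `"separation"`, `"ora"`, `"intraclass"`,
#' `"layout"`. Each step writes one TSV into `config$out_dir` with a
#' metadata header recording the seed and parameters; reruns with the same
#' config are byte-identical.
#'
#' Config keys (with defaults): `input`, `format` ("edgelist"),
#' `annotation` (path, optional; needed by separation/ora/intraclass),
#' `attr_name` ("terms"), `keep_lcc` (FALSE), `steps`, `algorithm` ("fc"),
#' `seed` (1), `reps` (100), `sample_fraction` (0.8), `n_perm` (100),
#' `out_dir`.
#'
#' @param config A named list or the path of a YAML file.
#' @return The output directory, invisibly; files as side effect.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(
    list(format = "edgelist", attr_name = "terms", keep_lcc = FALSE,
         algorithm = "fc", seed = 1L, reps = 100L, sample_fraction = 0.8,
         n_perm = 100L, steps = "centrality"),
    config
  )
  if (is.null(cfg$input)) stop("config$input is required", call. = FALSE)
  if (is.null(cfg$out_dir)) stop("config$out_dir is required", call. = FALSE)
  if (!file.exists(cfg$input)) {
    stop(sprintf("input not found: %s", cfg$input), call. = FALSE)
  }
  need_ann <- intersect(cfg$steps, c("separation", "ora", "intraclass"))
  if (length(need_ann) > 0L && is.null(cfg$annotation)) {
    stop(sprintf("steps %s require config$annotation",
                 paste(need_ann, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(cfg$annotation) && !file.exists(cfg$annotation)) {
    stop(sprintf("annotation not found: %s", cfg$annotation), call. = FALSE)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  net <- read_network(cfg$input, format = cfg$format)
  if (isTRUE(cfg$keep_lcc)) net <- largest_component(net)
  ann <- if (!is.null(cfg$annotation)) read_annotation(cfg$annotation) else NULL
  if (!is.null(ann)) net <- annotate_vertices(net, ann, cfg$attr_name)
  meta0 <- list(input = cfg$input, seed = cfg$seed, algorithm = cfg$algorithm)
  out <- function(name) file.path(cfg$out_dir, paste0(name, ".tsv"))
  clustering <- NULL
  get_clustering <- function() {
    if (is.null(clustering)) {
      clustering <<- cluster_network(net, cfg$algorithm, seed = cfg$seed)
    }
    clustering
  }
  for (step in cfg$steps) {
    switch(step,
      centrality = write_tsv_meta(calc_centrality(net), out("centrality"), meta0),
      powerlaw = {
        fit <- fit_powerlaw(igraph::degree(net))
        write_tsv_meta(glance(fit), out("powerlaw"), meta0)
      },
      entropy = {
        lcc <- largest_component(net)
        write_tsv_meta(tibble::as_tibble(perturb_entropy(lcc)), out("entropy"),
                       meta0)
      },
      cluster = write_tsv_meta(tidy(get_clustering()), out("membership"), meta0),
      summary = write_tsv_meta(clustering_summary(net, get_clustering()),
                               out("summary"), meta0),
      consensus = {
        cm <- consensus_matrix(net, cfg$algorithm,
                               sample_fraction = cfg$sample_fraction,
                               reps = cfg$reps, seed = cfg$seed)
        write_tsv_meta(tidy(cm), out("consensus"),
                       c(meta0, list(reps = cfg$reps,
                                     sample_fraction = cfg$sample_fraction)))
      },
      bridgeness = {
        cm <- consensus_matrix(net, cfg$algorithm,
                               sample_fraction = cfg$sample_fraction,
                               reps = cfg$reps, seed = cfg$seed)
        write_tsv_meta(bridgeness(cm, get_clustering()), out("bridgeness"),
                       c(meta0, list(reps = cfg$reps)))
      },
      separation = {
        res <- run_permutation_test(net, cfg$attr_name, pairs = "all",
                                    n_perm = cfg$n_perm, seed = cfg$seed)
        write_tsv_meta(res, out("separation"),
                       c(meta0, list(n_perm = cfg$n_perm)))
      },
      ora = {
        cl <- get_clustering()
        groups <- split(names(cl$membership), cl$membership)
        names(groups) <- paste0("cluster_", names(groups))
        write_tsv_meta(ora(groups, ann, vertex_ids(net)), out("ora"), meta0)
      },
      intraclass = {
        net2 <- annotate_vertices(net, ann, "class_first")
        cls <- vapply(strsplit(igraph::vertex_attr(net2, "class_first"), ";"),
                      function(x) if (length(x)) x[1L] else "none", character(1L))
        net2 <- igraph::set_vertex_attr(net2, "class", value = cls)
        write_tsv_meta(intra_class_edges(net2, "class", n_perm = cfg$n_perm,
                                         seed = cfg$seed),
                       out("intraclass"), c(meta0, list(n_perm = cfg$n_perm)))
      },
      layout = {
        cl <- get_clustering()
        write_tsv_meta(cluster_layout(net, cl, seed = cfg$seed), out("layout"),
                       meta0)
      },
      stop(sprintf("unknown step '%s'", step), call. = FALSE)
    )
  }
  invisible(cfg$out_dir)
}
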