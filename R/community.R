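# Community data model: species/resource nodes, metaweb links, experimental
# design and per-plot abundance samples, with tab-separated readers/writers.

#' Assemble and validate a community model
#'
#' Bundles the four tables the pipeline consumes: node traits, the metaweb of
#' plausible feeding links, the experimental design, and the per-plot-period
#' abundance/cover samples. All cross references are validated; invalid input
#' is rejected with an informative error.
#'
#' @param nodes data frame with columns `id`, `role` (one of plant,
#'   static_resource, consumer), `guild` (none for basal nodes, else
#'   detritivore/herbivore/omnivore/predator), `stratum` (ground/herb/both for
#'   consumers, none for basal nodes), `body_length_mm` (positive or NA).
#' @param metaweb data frame with columns `resource_id`, `consumer_id`,
#'   `link_type` (integer 1-5). Direction is resource -> consumer.
#' @param design data frame with columns `plot_id`, `block_id`,
#'   `sown_richness`.
#' @param samples data frame with columns `plot_id`, `time_period`, `node_id`,
#'   `value`, `value_kind` (`cover` for plants, `count` for consumers). Plant
#'   cover is relative cover in `[0,1]`, already normalised so that covers sum
#'   to at most 1 within a plot-period.
#' @return an object of class `motifweb_community`.
#' @export
community <- function(nodes, metaweb, design, samples) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  metaweb <- as.data.frame(metaweb, stringsAsFactors = FALSE)
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table lacks column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(nodes, c("id", "role", "guild", "stratum", "body_length_mm"), "trait")
  need(metaweb, c("resource_id", "consumer_id", "link_type"), "metaweb")
  need(design, c("plot_id", "block_id", "sown_richness"), "design")
  need(samples, c("plot_id", "time_period", "node_id", "value", "value_kind"),
       "abundance")

  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
         call. = FALSE)
  bad <- !nodes$role %in% .roles
  if (any(bad))
    stop("unknown role for node(s): ", paste(nodes$id[bad], collapse = ", "),
         call. = FALSE)
  bad <- !nodes$guild %in% .guilds
  if (any(bad))
    stop("malformed guild for node(s): ", paste(nodes$id[bad], collapse = ", "),
         call. = FALSE)
  basal <- nodes$role != "consumer"
  if (any(basal & nodes$guild != "none"))
    stop("basal nodes must have guild 'none': ",
         paste(nodes$id[basal & nodes$guild != "none"], collapse = ", "),
         call. = FALSE)
  if (any(!basal & nodes$guild == "none"))
    stop("consumers must have a feeding guild: ",
         paste(nodes$id[!basal & nodes$guild == "none"], collapse = ", "),
         call. = FALSE)
  if (any(!nodes$stratum %in% .strata))
    stop("malformed stratum", call. = FALSE)
  if (any(nodes$stratum == "none" & !basal))
    stop("stratum 'none' is reserved for basal nodes", call. = FALSE)
  bl <- nodes$body_length_mm
  if (any(!is.na(bl) & bl <= 0))
    stop("body_length_mm must be positive where given", call. = FALSE)

  role_of <- setNames(nodes$role, nodes$id)

  metaweb$resource_id <- as.character(metaweb$resource_id)
  metaweb$consumer_id <- as.character(metaweb$consumer_id)
  metaweb$link_type <- as.integer(metaweb$link_type)
  unk <- setdiff(c(metaweb$resource_id, metaweb$consumer_id), nodes$id)
  if (length(unk))
    stop("metaweb references undeclared id(s): ",
         paste(unk, collapse = ", "), call. = FALSE)
  if (any(metaweb$resource_id == metaweb$consumer_id))
    stop("self-links (cannibalism) are excluded from the metaweb",
         call. = FALSE)
  if (anyDuplicated(metaweb[c("resource_id", "consumer_id")]))
    stop("duplicate metaweb link(s)", call. = FALSE)
  if (any(!metaweb$link_type %in% 1:5))
    stop("link_type must be in 1..5", call. = FALSE)
  if (any(role_of[metaweb$consumer_id] != "consumer"))
    stop("only consumers may appear as consumer_id in the metaweb",
         call. = FALSE)

  design$plot_id <- as.character(design$plot_id)
  design$block_id <- as.character(design$block_id)
  design$sown_richness <- as.integer(design$sown_richness)
  if (anyDuplicated(design$plot_id))
    stop("each plot must appear once in the design table", call. = FALSE)

  samples$plot_id <- as.character(samples$plot_id)
  samples$node_id <- as.character(samples$node_id)
  unk <- setdiff(samples$plot_id, design$plot_id)
  if (length(unk))
    stop("abundance table references undeclared plot(s): ",
         paste(unk, collapse = ", "), call. = FALSE)
  unk <- setdiff(samples$node_id, nodes$id)
  if (length(unk))
    stop("abundance table references undeclared id(s): ",
         paste(unk, collapse = ", "), call. = FALSE)
  if (any(!samples$value_kind %in% c("cover", "count")))
    stop("value_kind must be 'cover' or 'count'", call. = FALSE)
  kind_role <- role_of[samples$node_id]
  if (any(samples$value_kind == "cover" & kind_role != "plant"))
    stop("cover values are only valid for plant nodes", call. = FALSE)
  if (any(samples$value_kind == "count" & kind_role != "consumer"))
    stop("count values are only valid for consumer nodes", call. = FALSE)
  if (any(samples$value < 0)) stop("abundance values must be >= 0",
                                   call. = FALSE)
  cov <- samples[samples$value_kind == "cover", ]
  if (nrow(cov)) {
    tot <- tapply(cov$value, paste(cov$plot_id, cov$time_period), sum)
    if (any(tot > 1 + 1e-8))
      stop("plant cover sums exceed 1 within a plot-period", call. = FALSE)
  }

  structure(list(nodes = nodes, metaweb = metaweb, design = design,
                 samples = samples),
            class = "motifweb_community")
}

#' @exportS3Method base::print
print.motifweb_community <- function(x, ...) {
  cat("<motifweb_community>\n")
  cat(sprintf("  nodes:   %d (%d plants, %d static resources, %d consumers)\n",
              nrow(x$nodes), sum(x$nodes$role == "plant"),
              sum(x$nodes$role == "static_resource"),
              sum(x$nodes$role == "consumer")))
  cat(sprintf("  metaweb: %d links\n", nrow(x$metaweb)))
  cat(sprintf("  design:  %d plots, %d blocks, %d period(s)\n",
              nrow(x$design), length(unique(x$design$block_id)),
              length(unique(x$samples$time_period))))
  invisible(x)
}

#' Extract one plot-period sample
#'
#' @param comm a `motifweb_community`.
#' @param plot_id plot identifier.
#' @param time_period period identifier.
#' @return a list with the plot's block, sown richness, named plant cover and
#'   consumer abundance vectors, and the ids of the static resource nodes
#'   (assumed present on every plot).
#' @export
plot_sample <- function(comm, plot_id, time_period) {
  d <- comm$design[comm$design$plot_id == plot_id, ]
  if (!nrow(d)) stop("unknown plot: ", plot_id, call. = FALSE)
  s <- comm$samples[comm$samples$plot_id == plot_id &
                    comm$samples$time_period == time_period, ]
  cov <- s[s$value_kind == "cover" & s$value > 0, ]
  cnt <- s[s$value_kind == "count" & s$value > 0, ]
  list(plot_id = plot_id,
       block_id = d$block_id,
       time_period = time_period,
       sown_richness = d$sown_richness,
       plant_cover = setNames(cov$value, cov$node_id),
       consumer_abundance = setNames(cnt$value, cnt$node_id),
       static_resources = comm$nodes$id[comm$nodes$role == "static_resource"])
}

.comm_files <- c(nodes = "traits.tsv", metaweb = "metaweb.tsv",
                 samples = "abundance.tsv", design = "design.tsv")

#' Read a community model from tab-separated files
#'
#' Expects the four-file layout written by [write_community()]: `traits.tsv`,
#' `metaweb.tsv`, `abundance.tsv` and `design.tsv` (UTF-8, tab-separated, one
#' header row).
#'
#' @param dir directory containing the files.
#' @return a validated `motifweb_community`.
#' @export
read_community <- function(dir) {
  paths <- file.path(dir, .comm_files)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  tabs <- lapply(paths, read.delim, stringsAsFactors = FALSE,
                 colClasses = "character", fileEncoding = "UTF-8")
  names(tabs) <- names(.comm_files)
  tabs$nodes$body_length_mm <- as.numeric(tabs$nodes$body_length_mm)
  tabs$metaweb$link_type <- as.integer(tabs$metaweb$link_type)
  tabs$design$sown_richness <- as.integer(tabs$design$sown_richness)
  tabs$samples$value <- as.numeric(tabs$samples$value)
  community(tabs$nodes, tabs$metaweb, tabs$design, tabs$samples)
}

#' Write a community model to tab-separated files
#'
#' Rows are emitted in a canonical order (sorted by id / plot / period) so
#' repeated write-read cycles are byte-stable.
#'
#' @param comm a `motifweb_community`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_community <- function(comm, out_dir) {
  stopifnot(inherits(comm, "motifweb_community"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)

  nodes <- comm$nodes[order(comm$nodes$id), ]
  mw <- comm$metaweb[order(comm$metaweb$resource_id, comm$metaweb$consumer_id), ]
  des <- comm$design[order(comm$design$plot_id), ]
  smp <- comm$samples[order(comm$samples$plot_id, comm$samples$time_period,
                            comm$samples$node_id), ]
  tabs <- list(nodes = nodes, metaweb = mw, samples = smp, design = des)
  paths <- file.path(out_dir, .comm_files)
  names(paths) <- names(.comm_files)
  for (nm in names(tabs))
    write.table(tabs[[nm]], paths[[nm]], sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}
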