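#' Serialize network parameters to portable plain-text files
#'
#' Writes `<stem>_manifest.json` (layer names and sizes, wiring, freeze and
#' oral-trained flags, training hyperparameters) and `<stem>_params.tsv`
#' (one row per parameter: kind, connection or layer, row, column, value).
#'
#' @param net a `triangle_net`.
#' @param stem file path stem.
#' @return The stem, invisibly.
#' @export
write_network <- function(net, stem) {
  cfg <- net$config
  manifest <- list(
    layer_names = net$layer_names,
    layer_sizes = net$layer_sizes,
    wiring = cfg$wiring,
    frozen_conn = net$frozen_conn, frozen_bias = net$frozen_bias,
    oral_trained_conn = net$oral_trained_conn,
    oral_trained_bias = net$oral_trained_bias,
    steps_oral = cfg$steps_oral, steps_read = cfg$steps_read,
    oral_target_window = cfg$oral_target_window,
    read_target_window = cfg$read_target_window,
    att_clamp = cfg$att_clamp, att_target_window = cfg$att_target_window,
    learning_rate = cfg$learning_rate, init_range = cfg$init_range,
    init_act = cfg$init_act, loss = cfg$loss,
    seed = net$seed,
    package_version = as.character(utils::packageVersion("triread")))
  jsonlite::write_json(manifest, paste0(stem, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  rows <- vector("list", length(net$weights) + length(net$biases))
  for (k in seq_along(net$weights)) {
    w <- net$weights[[k]]
    idx <- which(!is.na(w), arr.ind = TRUE)
    rows[[k]] <- data.frame(kind = "weight", name = names(net$weights)[k],
                            row = idx[, 1], col = idx[, 2],
                            value = as.vector(w))
  }
  for (l in seq_along(net$biases)) {
    b <- net$biases[[l]]
    rows[[length(net$weights) + l]] <-
      data.frame(kind = "bias", name = net$layer_names[l],
                 row = seq_along(b), col = 0L, value = b)
  }
  tab <- do.call(rbind, rows)
  # full precision so the round trip is bit-identical
  tab$value <- sprintf("%.17g", tab$value)
  write.table(tab, paste0(stem, "_params.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' Load network parameters written by [write_network()]
#'
#' @param stem file path stem used when writing.
#' @param lexicon the `lexicon` the network was built for (rebuilds the
#'   configuration; layer sizes are checked against the manifest).
#' @return A `triangle_net` with the stored parameters and flags.
#' @export
read_network <- function(stem, lexicon) {
  man <- jsonlite::read_json(paste0(stem, "_manifest.json"),
                             simplifyVector = TRUE)
  sizes <- setNames(man$layer_sizes, man$layer_names)
  cfg <- triangle_config(
    lexicon,
    h_op = sizes[["h_op"]], h_os1 = sizes[["h_os1"]],
    h_os2 = sizes[["h_os2"]], h_ps = sizes[["h_ps"]],
    h_sp = sizes[["h_sp"]], att_p = sizes[["att_p"]], att_s = sizes[["att_s"]],
    steps_oral = man$steps_oral, steps_read = man$steps_read,
    oral_target_window = man$oral_target_window,
    read_target_window = man$read_target_window,
    att_clamp = man$att_clamp, att_target_window = man$att_target_window,
    learning_rate = man$learning_rate, init_range = man$init_range,
    init_act = man$init_act, loss = man$loss)
  if (!identical(unname(cfg$layer_sizes), as.integer(man$layer_sizes)))
    stop("manifest layer sizes do not match this lexicon's configuration")
  net <- init_network(cfg, seed = man$seed)
  tab <- read.delim(paste0(stem, "_params.tsv"), colClasses =
                      c("character", "character", "integer", "integer",
                        "numeric"))
  for (k in seq_along(net$weights)) {
    sel <- tab$kind == "weight" & tab$name == names(net$weights)[k]
    w <- net$weights[[k]]
    w[cbind(tab$row[sel], tab$col[sel])] <- tab$value[sel]
    net$weights[[k]] <- w
  }
  for (l in seq_along(net$biases)) {
    sel <- tab$kind == "bias" & tab$name == net$layer_names[l]
    net$biases[[l]][tab$row[sel]] <- tab$value[sel]
  }
  net$frozen_conn <- man$frozen_conn
  net$frozen_bias <- man$frozen_bias
  net$oral_trained_conn <- man$oral_trained_conn
  net$oral_trained_bias <- man$oral_trained_bias
  net
}
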