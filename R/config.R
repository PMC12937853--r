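# YAML run configs: full nesting of network / loss / augmentation / training
# settings; every training run writes its resolved config next to its
# outputs for auditability.

#' Write a training configuration to YAML
#'
#' @param cfg a [train_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  yaml::write_yaml(strip(cfg), path)
  invisible(path)
}

#' Read a training configuration from YAML
#'
#' Missing fields fall back to the package defaults; every section is
#' re-validated through its constructor.
#'
#' @param path YAML file written by [write_run_config()] or by hand.
#' @return a `train_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(ctor, values) {
    values <- values[names(values) %in% names(formals(ctor))]
    do.call(ctor, values)
  }
  net <- if (is.null(raw$network)) network_config() else build(network_config, raw$network)
  loss <- if (is.null(raw$loss)) loss_config() else build(loss_config, raw$loss)
  aug <- if (is.null(raw$augmentation)) augment_config() else build(augment_config, raw$augmentation)
  top <- raw[setdiff(names(raw), c("network", "loss", "augmentation"))]
  top <- top[names(top) %in% names(formals(train_config))]
  do.call(train_config, c(list(network = net, loss = loss, augmentation = aug), top))
}
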