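# File formats

All tabular files are tab-delimited UTF-8 TSV without quoting. Readers
error on missing required columns; numeric tables must not contain NA.

## Expression (`read_expression` / `write_expression`)

Genes in rows, samples in columns. The header row holds sample ids; the
first column holds gene symbols (its header name is ignored). Values are
non-negative reals, comparable within each sample (arbitrary units).
At least 2 genes and 1 sample; gene and sample ids unique.

    gene    s0001   s0002
    EMP3    12.1    3.4
    FERMT1  1.9     8.0

An optional alias table (`read_alias_map`: columns `alias`, `canonical`)
harmonizes symbols on read: rows mapping to the canonical symbol `unknown`
are dropped; duplicates after mapping keep the highest-mean row.
Multi-symbol strings (`A///B`, or the mangled `A.....B`) are treated as
opaque symbols and never split.

## Cluster labels (`read_labels` / `write_labels`)

Columns `sample_id`, `cluster`. One row per sample; duplicate sample ids
are an error. An optional `label_order` fixes the label set and order;
otherwise labels are sorted alphabetically.

## Survival (`read_survival` / `write_survival`)

Columns `sample_id`, `time`, `event`, optional `group`. `time` is survival
in days, strictly positive. `event` is **1 = observed event (death),
0 = censored**; this coding is fixed.

## Gene-pair features (`read_pairs` / `write_pairs`)

Columns `cluster`, `gene_a`, `gene_b` (the `ClusterLabel GeneA GeneB`
layout). Orientation is significant: the feature is
`value(gene_a) < value(gene_b)`. Within a cluster no gene may appear in
two pairs. Lines starting with `#` before the header carry
`# key: value` provenance comments written by `write_pairs`.

## Single cell (`read_single_cell` / `write_single_cell`)

A triple of files:

* counts: matrix-market (`.mtx`), **cells in rows**, genes in columns,
  non-negative;
* gene list: plain text, one symbol per line, length = number of matrix
  columns;
* cell metadata: TSV, one row per cell in matrix row order; must contain
  the columns used for grouping (typically `cell_type` and `condition`,
  e.g. a binary tumor genotype), optionally `donor`.
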