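# File formats

All text files are space/tab/comma delimited as noted, with a header row.

## Genotypes

`raw-matrix` dialect (default):

    id m00001 m00002 ...
    ind00001 0 2 ...

`plink-raw` dialect (PLINK `--recode A` layout; the six leading columns
are written as placeholders and skipped on read):

    FID IID PAT MAT SEX PHENOTYPE snp1_A snp2_T ...
    f1 i1 0 0 0 NA 0 2 ...

Codes must be 0/1/2 (copies of the counted allele); anything else —
including NA — is rejected with the individual/marker coordinates.

## Phenotypes

CSV with header `id,y,bv` (`bv` = true breeding value, present for
simulated data).

## QTL truth table

CSV with header `marker,panel_index,effect`; `panel_index` is the locus
index in the original simulated panel before monomorphic-locus removal.

## Chain traces (`write_trace()` / `read_trace()`)

* `<stem>.tsv` — scalar samples, one row per iteration including iteration
  0 (the initial state): `iter  mu  pi  sigma2_a  sigma2_e  n_included`.
* `<stem>.rds` — the full `chain_trace` object (thinned marker-effect and
  indicator samples, running mean, marker names, seed, sampler label,
  format version).  Binary container; round-trips exactly.

## Augmentations (`write_augmentation()` / `read_augmentation()`)

RDS container with `d`, `jitter`, the augmented rows (`J_tilde`,
`X_tilde`, or per-group blocks), and a fingerprint of the source genotype
matrix that is checked at sampling time.

## Run configuration

Flat `key = value` text, one pair per line; `#` comments and blank lines
ignored.  Keys mirror the CLI flags (dashes or underscores); flags given
on the command line win over file values.

## Diagnostics report (`write_report()`)

`key = value` text: `psrf.mu`, `psrf.pi`, `psrf.sigma2_a`,
`psrf.sigma2_e`, `converged`, `accuracy`, `n_iterations_used`, `burn_in`.
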