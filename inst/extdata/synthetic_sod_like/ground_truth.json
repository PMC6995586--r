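{"planted_pairs":[{"i":4,"j":16,"coupling":2},{"i":11,"j":24,"coupling":2}],"q":6,"L":30,"n_sweeps":50,"seed":42}
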