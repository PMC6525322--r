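[{"scenario":"full_one_item","variant":"full","kind":"one_item","steps":470,"config_hash":"eee64c630927327cdb950ecb401763fc","seed":2024,"every":20},{"scenario":"facilitation_only","variant":"facilitation_only","kind":"one_item","steps":470,"config_hash":"8887b4b44b2892c7278a746464c190c2","seed":2024,"every":20},{"scenario":"no_c_to_f_plasticity","variant":"no_c_to_f_plasticity","kind":"one_item","steps":470,"config_hash":"7e281d88e040edf660a16273480e686c","seed":2024,"every":20},{"scenario":"no_conjunctive_layer","variant":"no_conjunctive_layer","kind":"one_item","steps":470,"config_hash":"8506b9e51ab383072c0811bd87e10677","seed":2024,"every":20},{"scenario":"full_retrocue","variant":"full","kind":"retrocue","steps":530,"config_hash":"eee64c630927327cdb950ecb401763fc","seed":2024,"every":20},{"scenario":"full_pulse","variant":"full","kind":"pulse","steps":530,"config_hash":"eee64c630927327cdb950ecb401763fc","seed":2024,"every":20}]
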