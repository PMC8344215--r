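taxon	genus
Haematomyzus_elephantis	Haematomyzus
Microthoracius_praelongiceps	Microthoracius
Polyplax_reclinata	Polyplax
Polyplax_spinulosa	Polyplax
Polyplax_asiatica	Polyplax
Hoplopleura_akanezumi	Hoplopleura
Hoplopleura_kitti	Hoplopleura
Pediculus_schaeffi	Pediculus
Pediculus_capitis	Pediculus
Pediculus_humanus	Pediculus
Pthirus_pubis	Pthirus
Pedicinus_obtusus	Pedicinus
Pedicinus_badii	Pedicinus
Haematopinus_asini	Haematopinus
Haematopinus_apri	Haematopinus
Haematopinus_suis	Haematopinus
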