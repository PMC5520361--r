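species	BrPe0043	BrPe0014	BrPe0002	BrPe0024	BrPe0033	BrPe0003	BrPe0021	BrPe0031	BrPe0028	BrPe0006	BrPe0010	BrPe0036	BrPe0034	BrPe0042	BrPe0001	BrPe0032	BrPe0038	BrPe3011
Passiflora pohlii	-	-	-	-	-	-	-	-	-	-	-	-	+	+	+	+	+	+
Passiflora sclerophylla	-	-	-	-	+	-	-	-	+	-	-	-	+	+	+	+	+	+
Passiflora suberosa	-	-	-	-	-	-	-	-	+	+	+	-	+	+	+	+	+	+
Passiflora eichleriana	-	-	-	-	+	-	+	-	-	+	+	-	+	+	+	+	+	+
Passiflora hatschbachii	-	-	-	-	+	+	-	+	-	-	-	+	+	+	+	+	+	+
Passiflora picturata	-	-	-	-	-	-	-	-	+	+	+	+	+	+	+	+	+	+
Passiflora porophylla	-	+	-	-	-	-	-	+	+	+	-	+	+	+	-	+	+	+
Passiflora saxicola	-	-	-	-	-	-	-	+	+	-	+	+	+	+	+	+	+	+
Passiflora tricuspis	-	-	-	-	-	+	-	-	+	+	-	+	+	+	+	+	+	+
Passiflora araujoi	-	-	-	-	-	-	+	+	+	+	-	+	+	+	+	+	+	+
Passiflora auriculata	-	-	-	-	-	-	-	+	+	+	+	+	+	+	+	+	+	+
Passiflora edmundoi	-	-	-	-	-	+	-	-	+	+	+	+	+	+	+	+	+	+
Passiflora ferruginea	-	-	-	+	-	-	+	+	+	-	-	+	+	+	+	+	+	+
Passiflora haematostigma	-	-	-	+	+	-	-	-	+	+	-	+	+	+	+	+	+	+
Passiflora loefgrenii	-	-	-	+	-	-	+	-	-	+	+	+	+	+	+	+	+	+
Passiflora micropetala	-	-	-	+	-	-	-	+	+	-	+	+	+	+	+	+	+	+
Passiflora misera	-	-	-	+	-	-	+	-	+	+	+	-	+	+	+	+	+	+
Passiflora morifolia	-	-	-	-	-	+	+	-	-	+	+	+	+	+	+	+	+	+
Passiflora rubra	-	+	-	+	-	-	-	-	+	+	-	+	+	+	+	+	+	+
Passiflora vespertilio	-	-	-	-	-	-	-	+	+	+	+	+	+	+	+	+	+	+
Passiflora acuminata	-	-	-	-	-	-	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora caerulea	-	-	+	-	-	-	+	-	+	+	+	+	+	+	+	+	+	+
Passiflora capsularis	+	-	-	+	-	-	+	+	-	+	+	+	+	-	+	+	+	+
Passiflora cervii	-	-	-	+	-	-	-	+	+	+	+	+	+	+	+	+	+	+
Passiflora jilekii	-	-	-	+	-	-	+	+	+	+	+	-	+	+	+	+	+	+
Passiflora rhamnifolia	-	-	-	-	+	-	-	+	+	+	+	+	+	+	+	+	+	+
Passiflora tholozanii	-	-	-	-	-	+	-	+	+	+	+	+	+	+	+	+	+	+
Passiflora triloba	-	+	-	-	+	+	+	-	+	+	+	-	-	+	+	+	+	+
Passiflora vitifolia	+	-	-	-	+	-	-	+	+	+	+	+	-	+	+	+	+	+
Passiflora ambigua	+	-	-	+	-	-	+	-	+	+	+	+	+	+	+	+	+	+
Passiflora biflora	-	-	-	-	-	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora boticarioana	-	-	+	+	+	+	-	-	-	+	+	+	+	+	+	+	+	+
Passiflora cerradense	-	-	-	+	+	+	-	-	+	+	+	+	+	+	+	+	+	+
Passiflora chlorina	+	-	-	+	+	+	-	-	-	+	+	+	+	+	+	+	+	+
Passiflora cincinnata	-	-	-	+	+	+	-	-	+	+	+	+	+	+	+	+	+	+
Passiflora elegans	-	-	+	-	+	+	-	+	-	+	+	+	+	+	+	+	+	+
Passiflora foetida	-	-	-	-	+	+	+	+	-	+	+	+	+	+	+	+	+	+
Passiflora gardneri	-	-	+	+	+	+	+	-	-	-	+	+	+	+	+	+	+	+
Passiflora gibertii	-	-	-	+	+	-	+	+	+	+	+	+	+	-	+	+	+	+
Passiflora incarnata	+	-	-	-	-	-	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora junqueirae	-	-	+	-	+	-	+	+	+	-	+	+	+	+	+	+	+	+
Passiflora kermesina	-	+	+	-	-	+	-	+	+	-	+	+	+	+	+	+	+	+
Passiflora organensis	-	-	-	-	-	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora quadrifarial	-	-	-	-	+	+	-	+	+	+	+	+	+	+	+	+	+	+
Passiflora trintae	-	-	-	+	-	+	+	-	+	+	+	+	+	+	+	+	+	+
Passiflora villosa	-	-	+	-	+	+	-	+	-	+	+	+	+	+	+	+	+	+
Passiflora actinia	-	-	+	-	+	+	+	-	+	+	+	+	+	+	+	+	+	+
Passiflora amethystina	-	-	+	+	+	-	+	-	+	+	+	+	+	+	+	+	+	+
Passiflora cerasina	-	-	-	-	+	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora coccinea	-	-	-	-	+	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora decaisneana	-	-	-	-	+	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora galbana	-	-	+	+	-	+	+	+	+	-	+	+	+	+	+	+	+	+
Passiflora hypoglauca	-	-	+	-	+	+	-	+	+	+	+	+	+	+	+	+	+	+
Passiflora malacophylla	-	-	+	+	+	+	+	-	-	+	+	+	+	+	+	+	+	+
Passiflora miersii	-	-	+	-	+	+	+	+	+	-	+	+	+	+	+	+	+	+
Passiflora mucronata	-	-	-	+	+	+	+	+	-	+	+	+	+	+	+	+	+	+
Passiflora quadrangularis	-	-	-	-	+	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora quadriglandulosa	+	-	-	-	+	+	+	+	+	+	+	-	+	+	+	+	+	+
Passiflora riparia	-	-	-	-	+	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora sidaefolia	-	-	-	+	+	+	-	+	+	+	+	+	+	+	+	+	+	+
Passiflora subrotunda	-	-	-	+	+	-	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora variolata	-	-	-	-	+	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora bahiensis	+	-	-	+	-	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora luetzelburgii	-	-	+	+	+	+	+	-	+	+	+	+	+	+	+	+	+	+
Passiflora mendoncaei	-	-	+	-	+	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora nitida	-	+	-	-	+	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora racemosa	-	-	+	-	+	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora recurva	-	-	+	-	+	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora speciosa	+	+	-	-	+	+	+	-	+	+	+	+	+	+	+	+	+	+
Passiflora glandulosa	+	+	-	+	-	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora laurifolia	+	-	+	+	-	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora ligularis	-	-	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora maliformis	-	-	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora odontophylla	-	+	-	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora pedata	-	-	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora tenuifila	-	-	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora alata	-	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora setacea	-	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+
Passiflora edulis	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+	+
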