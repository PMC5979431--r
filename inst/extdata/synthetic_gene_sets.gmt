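proteolysis_synthetic	synthetic demo set (random membership, not curated biology)	g00234	g00390	g01037	g01207	g01506	g01669	g01673	g01965	g02088	g02340	g02380	g02892	g02967	g03163	g03408	g03570	g04072	g04224	g04575	g04787	g04836	g05259	g05409	g05441	g05515	g05679	g06185	g06632	g06902	g07190	g07238	g07606	g07685	g07719	g07764	g08547	g08700	g08746	g08941	g09038	g09043	g09106	g09841	g09858	g09978
lipid_metabolism_synthetic	synthetic demo set (random membership, not curated biology)	g00070	g00085	g00150	g00159	g00297	g00330	g00339	g00735	g00885	g01100	g01379	g01459	g01531	g01656	g01802	g01868	g01979	g02102	g02110	g02143	g02481	g02569	g02601	g02787	g02789	g02990	g03161	g03181	g03581	g03592	g03828	g03946	g04223	g04226	g04254	g04319	g04722	g05172	g05524	g05657	g05831	g05909	g06234	g06858	g06909	g06911	g07024	g07408	g07717	g07797	g07878	g07977	g08191	g08361	g08517	g08688	g08930	g09331	g09855	g09964
chromatin_remodeling_synthetic	synthetic demo set (random membership, not curated biology)	g00122	g00770	g01133	g01357	g01431	g01607	g01751	g01757	g01843	g02003	g02101	g02568	g03188	g03267	g03703	g03765	g04147	g04617	g05530	g05987	g06181	g06466	g06886	g07052	g07072	g07500	g07835	g07903	g08197	g08353	g08594	g08769	g09185	g09421	g09998
neuronal_function_synthetic	synthetic demo set (random membership, not curated biology)	g00008	g00217	g00266	g00325	g00431	g00673	g00692	g00738	g00853	g00908	g00995	g01013	g01092	g01169	g01249	g01259	g01400	g01565	g01775	g02064	g02376	g02388	g02402	g02526	g02528	g03004	g03113	g03184	g03396	g03438	g03546	g03727	g03929	g04317	g04447	g04763	g04891	g04974	g05124	g05248	g05281	g05294	g05295	g05304	g05364	g05411	g05475	g05779	g05899	g06232	g06329	g06332	g06951	g07408	g07421	g07695	g07715	g07819	g07841	g07941	g07978	g07996	g08272	g08715	g08807	g08835	g08857	g08866	g08954	g08987	g09012	g09095	g09349	g09460	g09562	g09597	g09849	g09909	g09927	g09970
stress_response_synthetic	synthetic demo set (random membership, not curated biology)	g00253	g00539	g00625	g00657	g00915	g01147	g01222	g01366	g01442	g01449	g01643	g02255	g02308	g02421	g02694	g03568	g03689	g03815	g03945	g04029	g04231	g04338	g04609	g05076	g05446	g05462	g05809	g05884	g05967	g06098	g06351	g06468	g06993	g07393	g07869	g07972	g08151	g08535	g08571	g08732	g08983	g09002	g09082	g09110	g09136	g09248	g09355	g09366	g09520	g09548
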