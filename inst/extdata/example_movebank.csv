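timestamp,location-long,location-lat,individual-local-identifier
2020-01-01 00:00:00Z,23.5179885069503,-19.499328157243,ex01
2020-01-01 02:00:00Z,23.5214260723605,-19.5008485487092,ex01
2020-01-01 04:00:00Z,23.523868555382,-19.503825613789,ex01
2020-01-01 06:00:00Z,23.5221298539969,-19.5027358451908,ex01
2020-01-01 08:00:00Z,23.5204135341077,-19.5019758678426,ex01
2020-01-01 10:00:00Z,23.5203396909783,-19.5040023498938,ex01
2020-01-01 12:00:00Z,23.5148501411159,-19.5080135286638,ex01
2020-01-01 14:00:00Z,23.5109471946964,-19.5089187316313,ex01
2020-01-01 16:00:00Z,23.5045300300833,-19.5071998268591,ex01
2020-01-01 18:00:00Z,23.5001515085414,-19.5092776733906,ex01
2020-01-01 20:00:00Z,23.501787908537,-19.5089183419026,ex01
2020-01-01 22:00:00Z,23.4978153739789,-19.5100128931542,ex01
2020-01-02 00:00:00Z,23.4970892279844,-19.5080927713294,ex01
2020-01-02 02:00:00Z,23.4970805091475,-19.5031512043602,ex01
2020-01-02 04:00:00Z,23.4974793718072,-19.5037635707945,ex01
2020-01-02 06:00:00Z,23.503384020536,-19.5025069304166,ex01
2020-01-02 08:00:00Z,23.5066209273072,-19.497923649627,ex01
2020-01-02 10:00:00Z,23.5069960583942,-19.4908194186929,ex01
2020-01-02 12:00:00Z,23.5055111283421,-19.4899893471023,ex01
2020-01-02 14:00:00Z,23.5040732362521,-19.4885954682341,ex01
2020-01-02 16:00:00Z,23.5004429177276,-19.4922406191936,ex01
2020-01-02 18:00:00Z,23.5000121109952,-19.4953679031758,ex01
2020-01-02 20:00:00Z,23.5030152593875,-19.493990169231,ex01
2020-01-02 22:00:00Z,23.504541054669,-19.4922776353196,ex01
2020-01-03 00:00:00Z,23.5041870456137,-19.4913379749243,ex01
2020-01-01 00:00:00Z,23.5098749272221,-19.5188119352991,ex02
2020-01-01 02:00:00Z,23.5113696448903,-19.5189893538184,ex02
2020-01-01 04:00:00Z,23.5136115437119,-19.5197415795465,ex02
2020-01-01 06:00:00Z,23.5185491990635,-19.5185866168734,ex02
2020-01-01 08:00:00Z,23.5150106851513,-19.5158699442878,ex02
2020-01-01 10:00:00Z,23.5074498452777,-19.512755160234,ex02
2020-01-01 12:00:00Z,23.5043124630843,-19.5113422670365,ex02
2020-01-01 14:00:00Z,23.5023643707292,-19.5079597097037,ex02
2020-01-01 16:00:00Z,23.5016150986213,-19.499451058257,ex02
2020-01-01 18:00:00Z,23.5011192682295,-19.4970633802547,ex02
2020-01-01 20:00:00Z,23.5067224290488,-19.5007205861924,ex02
2020-01-01 22:00:00Z,23.5049996146409,-19.5046892622524,ex02
2020-01-02 00:00:00Z,23.4993926508806,-19.5032378228961,ex02
2020-01-02 02:00:00Z,23.4955379491794,-19.4988539525867,ex02
2020-01-02 04:00:00Z,23.4951595478505,-19.4910709211251,ex02
2020-01-02 06:00:00Z,23.4975529735028,-19.4880596043021,ex02
2020-01-02 08:00:00Z,23.4986333061991,-19.4873104458503,ex02
2020-01-02 10:00:00Z,23.5016774386552,-19.4893130624202,ex02
2020-01-02 12:00:00Z,23.502675567475,-19.489146294294,ex02
2020-01-02 14:00:00Z,23.5025474076227,-19.4866507941546,ex02
2020-01-02 16:00:00Z,23.4980854115081,-19.4875993351099,ex02
2020-01-02 18:00:00Z,23.4955372685707,-19.4838847534566,ex02
2020-01-02 20:00:00Z,23.4946490277669,-19.4807840005584,ex02
2020-01-02 22:00:00Z,23.4924427276519,-19.484100465427,ex02
2020-01-03 00:00:00Z,23.4976550711067,-19.4858617854258,ex02
2020-01-01 00:00:00Z,23.510497794793,-19.4864121461113,ex03
2020-01-01 02:00:00Z,23.5055902496642,-19.4860820208601,ex03
2020-01-01 04:00:00Z,23.5059546439413,-19.4855834773607,ex03
2020-01-01 06:00:00Z,23.5061169824364,-19.4836909716392,ex03
2020-01-01 08:00:00Z,23.5069996404625,-19.4819807452954,ex03
2020-01-01 10:00:00Z,23.5059195761828,-19.4810130641461,ex03
2020-01-01 12:00:00Z,23.5063145191909,-19.4830157175512,ex03
2020-01-01 14:00:00Z,23.5061692810786,-19.4837521639778,ex03
2020-01-01 16:00:00Z,23.5010124478856,-19.4851523662151,ex03
2020-01-01 18:00:00Z,23.4984219563318,-19.4844217522482,ex03
2020-01-01 20:00:00Z,23.4983255859876,-19.4859937156719,ex03
2020-01-01 22:00:00Z,23.4988117977155,-19.4880059824814,ex03
2020-01-02 00:00:00Z,23.4978798147504,-19.4855393646301,ex03
2020-01-02 02:00:00Z,23.4954055024533,-19.4860745175495,ex03
2020-01-02 04:00:00Z,23.4922203386577,-19.4869279222618,ex03
2020-01-02 06:00:00Z,23.4915776282523,-19.4916853202597,ex03
2020-01-02 08:00:00Z,23.4898353454259,-19.4951473381205,ex03
2020-01-02 10:00:00Z,23.4862814751731,-19.4945932143071,ex03
2020-01-02 12:00:00Z,23.4880160416252,-19.4961322011417,ex03
2020-01-02 14:00:00Z,23.4903284173526,-19.498779710083,ex03
2020-01-02 16:00:00Z,23.4954140244145,-19.4993650416127,ex03
2020-01-02 18:00:00Z,23.4945911834642,-19.4974031215777,ex03
2020-01-02 20:00:00Z,23.4923869115879,-19.4928690327321,ex03
2020-01-02 22:00:00Z,23.4888226834971,-19.4957019863163,ex03
2020-01-03 00:00:00Z,23.4891342117217,-19.4944986599508,ex03
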